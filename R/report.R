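## Reporting conventions: median (p5-p95) summaries and 2D breathing-angle
## histograms.

#' Summarize a series as median with 5-95 percentiles
#'
#' Percentiles use linear interpolation between order statistics (the
#' type-7 rule), the convention fixed for all tabulated summaries.
#'
#' @param values Nonempty numeric vector.
#' @return Object of class `nuc_summary`: list with `median`, `p5`,
#'   `p95`, `n`.
#' @export
summarize_series <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty series")
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  structure(list(median = q[2L], p5 = q[1L], p95 = q[3L],
                 n = length(values)),
            class = "nuc_summary")
}

#' Format a summary as "median (p5-p95)"
#'
#' @param s A `nuc_summary`.
#' @param digits Decimal places (default 1).
#' @return Character scalar, e.g. `"49.2 (48.3–51.0)"` (en dash).
#' @export
format_summary <- function(s, digits = 1L) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "–", fmt, ")"),
          s$median, s$p5, s$p95)
}

#' @export
print.nuc_summary <- function(x, ...) {
  cat(format_summary(x), sprintf("[n=%d]\n", x$n))
  invisible(x)
}

#' Parse a "median (p5-p95)" string back into a summary
#'
#' @param text Character scalar such as `"49.2 (48.3–51.0)"`.
#' @return A `nuc_summary` (with `n = NA`).
#' @export
parse_summary <- function(text) {
  m <- regmatches(text,
                  regexec("^\\s*(-?[0-9.]+)\\s*\\((-?[0-9.]+)[–-](-?[0-9.]+)\\)\\s*$",
                          text))[[1L]]
  if (length(m) != 4L) stop("cannot parse summary string: ", text)
  structure(list(median = as.numeric(m[2L]), p5 = as.numeric(m[3L]),
                 p95 = as.numeric(m[4L]), n = NA_integer_),
            class = "nuc_summary")
}

#' 2D histogram of breathing angles
#'
#' Counts (gamma1, gamma2) samples on a regular grid (default 1-degree
#' bins); the conventional display contours sit at 1 and 100 counts.
#' Multiple ensembles (e.g. free vs TF-bound) are kept as separate grids
#' on a common binning.
#'
#' @param gamma1,gamma2 Numeric vectors (degrees), or a named list of such
#'   pairs for a multi-ensemble overlay, e.g.
#'   `list(free = list(g1, g2), bound = list(g1, g2))` passed as `gamma1`.
#' @param binwidth Bin width in degrees (> 0).
#' @param levels Contour levels (counts).
#' @return Object of class `nuc_gamma_hist`: list with `breaks1`,
#'   `breaks2`, `counts` (matrix, or named list of matrices), `levels`.
#' @export
gamma_histogram2d <- function(gamma1, gamma2 = NULL, binwidth = 1,
                              levels = c(1, 100)) {
  stopifnot_scalar_number(binwidth, "binwidth", positive = TRUE)
  ensembles <- if (is.list(gamma1)) gamma1 else list(all = list(gamma1, gamma2))
  allg1 <- unlist(lapply(ensembles, `[[`, 1L))
  allg2 <- unlist(lapply(ensembles, `[[`, 2L))
  if (!length(allg1)) stop("empty angle series")
  if (length(allg1) != length(allg2)) stop("gamma1/gamma2 length mismatch")
  br <- function(x) {
    lo <- floor(min(x) / binwidth) * binwidth
    hi <- ceiling(max(x) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    seq(lo, hi, by = binwidth)
  }
  b1 <- br(allg1); b2 <- br(allg2)
  one <- function(e) {
    i <- findInterval(e[[1L]], b1, rightmost.closed = TRUE)
    j <- findInterval(e[[2L]], b2, rightmost.closed = TRUE)
    m <- matrix(0L, length(b1) - 1L, length(b2) - 1L)
    for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
    m
  }
  counts <- lapply(ensembles, one)
  if (length(counts) == 1L) counts <- counts[[1L]]
  structure(list(breaks1 = b1, breaks2 = b2, counts = counts,
                 levels = levels),
            class = "nuc_gamma_hist")
}

#' @export
print.nuc_gamma_hist <- function(x, ...) {
  n <- if (is.list(x$counts)) sum(vapply(x$counts, sum, 0)) else sum(x$counts)
  cat(sprintf("<nuc_gamma_hist> %d samples, %dx%d bins, contours {%s}\n",
              n, length(x$breaks1) - 1L, length(x$breaks2) - 1L,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Export a 2D angle histogram as long-format CSV
#'
#' @param hist A `nuc_gamma_hist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gamma_histogram <- function(hist, path) {
  grids <- if (is.list(hist$counts)) hist$counts else list(all = hist$counts)
  mid <- function(b) (b[-1L] + b[-length(b)]) / 2
  rows <- list()
  for (nm in names(grids)) {
    g <- grids[[nm]]
    rows[[nm]] <- data.frame(
      ensemble = nm,
      gamma1_deg = rep(mid(hist$breaks1), times = ncol(g)),
      gamma2_deg = rep(mid(hist$breaks2), each = nrow(g)),
      count = as.vector(g))
  }
  write_table(do.call(rbind, rows), path, digits = 1L)
}
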