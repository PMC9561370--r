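## Heavy-atom contact counting, contact series, stable-contact profiles,
## and the subdomain x gyre contact table.

#' Define a contact specification
#'
#' A contact is two non-hydrogen atoms closer than `cutoff` (strictly;
#' default 4.5 Angstrom). At `"atom-pair"` granularity the count is the
#' number of such unordered cross pairs; at `"residue-bp"` granularity it
#' is the number of (residue, base-pair) combinations with at least one
#' contacting atom pair.
#'
#' @param groupA,groupB `nuc_selection` objects or atom index vectors.
#' @param cutoff Contact cutoff in Angstrom (> 0).
#' @param granularity `"atom-pair"` or `"residue-bp"`.
#' @return Object of class `nuc_contact_spec`.
#' @export
contact_spec <- function(groupA, groupB, cutoff = 4.5,
                         granularity = c("atom-pair", "residue-bp")) {
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  structure(list(groupA = groupA, groupB = groupB, cutoff = cutoff,
                 granularity = match.arg(granularity)),
            class = "nuc_contact_spec")
}

resolve_contact_groups <- function(frame, spec, topology) {
  ia <- resolve_selection(spec$groupA, frame, topology)
  ib <- resolve_selection(spec$groupB, frame, topology)
  h <- frame$atoms$element == "H"
  ia <- ia[!h[ia]]; ib <- ib[!h[ib]]
  if (!length(ia) || !length(ib))
    stop("empty contact group after hydrogen exclusion")
  if (length(intersect(ia, ib)))
    stop("contact groups must be disjoint")
  list(ia = ia, ib = ib)
}

## Logical contact matrix (strict < cutoff) between two index sets.
contact_matrix <- function(frame, ia, ib, cutoff) {
  cross_dist2(frame$xyz[ia, , drop = FALSE],
              frame$xyz[ib, , drop = FALSE]) < cutoff * cutoff
}

## residue-level keys: residues for proteins, base pairs for DNA
residue_keys <- function(atoms, idx) {
  k <- ifelse(!is.na(atoms$bp[idx]),
              paste0("bp:", atoms$bp[idx]),
              paste0(atoms$role[idx], ":", atoms$resno[idx]))
  k
}

#' Count contacts between two groups in one frame
#'
#' @param frame A `nuc_frame`.
#' @param spec A `nuc_contact_spec`.
#' @param topology Needed for declarative selections.
#' @return Integer contact count.
#' @examples
#' # two heavy atoms at 4.4 A -> 1 contact; at 4.6 A -> 0
#' @export
count_contacts <- function(frame, spec, topology = NULL) {
  g <- resolve_contact_groups(frame, spec, topology)
  m <- contact_matrix(frame, g$ia, g$ib, spec$cutoff)
  if (spec$granularity == "atom-pair") return(sum(m))
  ka <- residue_keys(frame$atoms, g$ia)
  kb <- residue_keys(frame$atoms, g$ib)
  touched <- which(m, arr.ind = TRUE)
  if (!nrow(touched)) return(0L)
  length(unique(paste(ka[touched[, 1L]], kb[touched[, 2L]], sep = "|")))
}

#' Per-frame contact series over a trajectory
#'
#' @param trajectory A `nuc_trajectory`.
#' @param spec A `nuc_contact_spec`.
#' @param topology A `nuc_topology`.
#' @return Data frame with columns `frame`, `count`.
#' @export
contact_series <- function(trajectory, spec, topology = NULL) {
  nf <- n_frames(trajectory)
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    counts[i] <- tryCatch(
      count_contacts(get_frame(trajectory, i), spec, topology),
      error = function(e) stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  data.frame(frame = seq_len(nf), count = counts)
}

#' Stable-contact profile between tail residues and DNA base pairs
#'
#' Occupancy of each (residue, base pair) combination = fraction of frames
#' with at least one heavy-atom pair closer than `cutoff`. A contact is
#' stable if its occupancy is strictly greater than `threshold` (default
#' 0.75: present for more than 75% of the analyzed frames).
#'
#' @param trajectory A `nuc_trajectory`.
#' @param tail_selection,dna_selection Selections or atom indices.
#' @param topology A `nuc_topology`.
#' @param cutoff Contact cutoff (Angstrom).
#' @param threshold Stability threshold on occupancy (strict).
#' @return Object of class `nuc_stable_profile`: list with `profile` (long
#'   data frame: `role`, `resno`, `bp`, `occupancy`, `stable`) and
#'   `per_bp` (marginal count of stable residues per base pair).
#' @export
stable_contact_profile <- function(trajectory, tail_selection, dna_selection,
                                   topology = NULL, cutoff = 4.5,
                                   threshold = 0.75) {
  nf <- n_frames(trajectory)
  if (nf < 1L) stop("zero frames")
  fr1 <- get_frame(trajectory, 1L)
  ia <- resolve_selection(tail_selection, fr1, topology)
  ib <- resolve_selection(dna_selection, fr1, topology)
  h <- fr1$atoms$element == "H"
  ia <- ia[!h[ia]]; ib <- ib[!h[ib]]
  if (!length(ia) || !length(ib)) stop("empty group after hydrogen exclusion")

  a <- fr1$atoms
  res_key <- paste(a$role[ia], a$resno[ia], sep = ":")
  bp_key <- a$bp[ib]
  if (anyNA(bp_key)) stop("dna_selection contains non-DNA atoms")
  res_f <- factor(res_key, levels = unique(res_key))
  bp_f <- factor(bp_key, levels = sort(unique(bp_key)))
  ind <- function(f) {                            # atoms x levels indicator
    m <- matrix(0, length(f), nlevels(f))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  Ra <- ind(res_f)
  Rb <- ind(bp_f)

  acc <- matrix(0L, nlevels(res_f), nlevels(bp_f))
  for (i in seq_len(nf)) {
    fr <- get_frame(trajectory, i)
    m <- contact_matrix(fr, ia, ib, cutoff)
    inc <- (crossprod(Ra, m %*% Rb) > 0)
    acc <- acc + inc
  }
  occ <- acc / nf
  role_res <- strsplit(levels(res_f), ":", fixed = TRUE)
  profile <- data.frame(
    role = rep(vapply(role_res, `[[`, "", 1L), times = nlevels(bp_f)),
    resno = rep(as.integer(vapply(role_res, `[[`, "", 2L)),
                times = nlevels(bp_f)),
    bp = rep(as.integer(levels(bp_f)), each = nlevels(res_f)),
    occupancy = as.vector(occ))
  profile$stable <- profile$occupancy > threshold
  per_bp <- stats::aggregate(stable ~ bp, data = profile, FUN = sum)
  names(per_bp)[2L] <- "n_stable_residues"
  structure(list(profile = profile, per_bp = per_bp,
                 threshold = threshold, cutoff = cutoff, n_frames = nf),
            class = "nuc_stable_profile")
}

#' @export
print.nuc_stable_profile <- function(x, ...) {
  cat(sprintf("<nuc_stable_profile> %d residue x bp cells, %d stable (>%.0f%% of %d frames)\n",
              nrow(x$profile), sum(x$profile$stable), 100 * x$threshold,
              x$n_frames))
  invisible(x)
}

#' TF-subdomain vs DNA-gyre contact table
#'
#' Summarizes per-frame heavy-atom contact counts between each TF
#' subdomain (POU_S, POU_HD) and DNA bases vs backbone of the inner gyre,
#' the outer gyres, and all DNA, as median (5th-95th percentile) --
#' the reporting convention of per-simulation contact tables.
#'
#' @param trajectory A `nuc_trajectory`.
#' @param topology A `nuc_topology` with TF subdomains.
#' @param cutoff Contact cutoff (Angstrom).
#' @return Data frame with columns `subdomain`, `dna_part`, `gyre`,
#'   `median`, `p5`, `p95`, `n`, `formatted`.
#' @export
subdomain_gyre_contact_table <- function(trajectory, topology, cutoff = 4.5) {
  if (is.null(topology$tf_subdomains))
    stop("topology declares no TF subdomains")
  gyres <- c(inner = "inner_gyre", outer = "outer_gyres", all = NA)
  out <- list()
  for (sd in c("POU_S", "POU_HD")) {
    for (part in c("base", "backbone")) {
      for (gy in names(gyres)) {
        region <- gyres[[gy]]
        dna_sel <- atom_selection(roles = "DNA",
                                  dna_region = if (is.na(region)) NULL
                                               else region,
                                  dna_part = part)
        spec <- contact_spec(atom_selection(roles = "TF", subdomain = sd),
                             dna_sel, cutoff = cutoff)
        cs <- contact_series(trajectory, spec, topology)
        s <- summarize_series(cs$count)
        out[[length(out) + 1L]] <- data.frame(
          subdomain = sd, dna_part = part, gyre = gy,
          median = s$median, p5 = s$p5, p95 = s$p95, n = s$n,
          formatted = format_summary(s, digits = 0L))
      }
    }
  }
  do.call(rbind, out)
}
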