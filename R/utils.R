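#' @keywords internal
"_PACKAGE"

## Small internal helpers shared across modules.

#' Unit vector
#' @noRd
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @noRd
rotation_about <- function(axis, angle) {
  u <- unit(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * c0 + s0 * K + (1 - c0) * tcrossprod(u)
}

#' Minimal rotation carrying unit vector a onto unit vector b
#' @noRd
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  ax <- c(a[2L] * b[3L] - a[3L] * b[2L],
          a[3L] * b[1L] - a[1L] * b[3L],
          a[1L] * b[2L] - a[2L] * b[1L])
  s <- sqrt(sum(ax^2))
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3L))
    ## antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit(p - sum(p * a) * a)
    return(rotation_about(perp, pi))
  }
  rotation_about(ax, atan2(s, d))
}

#' Squared cross-distance matrix between two coordinate sets
#'
#' Computed from explicit per-axis differences so that counting against a
#' squared cutoff is arithmetic-identical to a naive double loop.
#' @noRd
cross_dist2 <- function(a, b) {
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  dz <- outer(a[, 3L], b[, 3L], "-")
  dx * dx + dy * dy + dz * dz
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
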