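## Collective variables (distanceInv, coordination number) and declarative
## harmonic-wall / steered bias protocols with Colvars-style export.

#' distanceInv specification
#'
#' The weighted-minimum-distance collective variable
#' `d[n] = ( (1/(N1*N2)) * sum_ij (1/||dij||)^n )^(-1/n)`,
#' which approaches the minimal inter-group distance from above as the even
#' exponent `n` grows. `n = 100` approximates the minimum closely while
#' remaining smooth. Groups conventionally use backbone-trace atoms
#' (C-alpha for protein, P for DNA).
#'
#' @param group1,group2 `nuc_selection` objects or atom index vectors.
#' @param n Even integer exponent >= 2 (default 100).
#' @return Object of class `nuc_distance_inv_spec`.
#' @export
distance_inv_spec <- function(group1, group2, n = 100L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n %% 2L != 0L)
    stop("'n' must be an even integer >= 2")
  structure(list(group1 = group1, group2 = group2, n = n),
            class = c("nuc_distance_inv_spec", "nuc_cv_spec"))
}

#' Coordination-number specification
#'
#' `C = sum_ij (1 - r^n) / (1 - r^m)` with `r = |xi - xj| / d0`, a smooth
#' count of inter-group atom pairs within the threshold distance `d0`
#' (default 4.0 Angstrom, exponents n = 6, m = 12). With `m = 2n` the
#' ratio factorizes to the singularity-free form `1 / (1 + r^n)`,
#' continuous (value 1/2) at `r = 1`.
#'
#' @param group1,group2 `nuc_selection` objects or atom index vectors.
#' @param d0 Threshold distance in Angstrom (> 0).
#' @param n,m Exponents, `m > n > 0`.
#' @return Object of class `nuc_coordination_spec`.
#' @export
coordination_spec <- function(group1, group2, d0 = 4.0, n = 6L, m = 12L) {
  stopifnot_scalar_number(d0, "d0", positive = TRUE)
  n <- as.integer(n); m <- as.integer(m)
  if (!(m > n && n > 0L)) stop("exponents must satisfy m > n > 0")
  structure(list(group1 = group1, group2 = group2, d0 = d0, n = n, m = m),
            class = c("nuc_coordination_spec", "nuc_cv_spec"))
}

cv_group_xyz <- function(frame, sel, topology) {
  idx <- resolve_selection(sel, frame, topology)
  h <- frame$atoms$element == "H"
  idx <- idx[!h[idx]]
  if (!length(idx)) stop("empty collective-variable group")
  frame$xyz[idx, , drop = FALSE]
}

#' Evaluate distanceInv on a frame
#'
#' Overflow-safe for large `n`: the minimum distance is factored out before
#' exponentiation. Coincident atoms across groups (zero distance) return 0
#' with a warning (the limit of the formula).
#'
#' @param frame A `nuc_frame`.
#' @param spec A `nuc_distance_inv_spec`.
#' @param topology Needed for declarative groups.
#' @return Value in Angstrom.
#' @export
distance_inv <- function(frame, spec, topology = NULL) {
  a <- cv_group_xyz(frame, spec$group1, topology)
  b <- cv_group_xyz(frame, spec$group2, topology)
  d2 <- cross_dist2(a, b)
  dmin2 <- min(d2)
  if (dmin2 == 0) {
    warning("coincident atoms across groups: distanceInv -> 0")
    return(0)
  }
  ## d[n] = dmin * ( mean( (dmin/d)^n ) )^(-1/n); all ratios <= 1
  r2 <- dmin2 / d2
  m <- mean(r2^(spec$n / 2))
  sqrt(dmin2) * m^(-1 / spec$n)
}

#' Evaluate the coordination number on a frame
#'
#' @param frame A `nuc_frame`.
#' @param spec A `nuc_coordination_spec`.
#' @param topology Needed for declarative groups.
#' @return Dimensionless value in `[0, N1*N2]`.
#' @export
coordination_number <- function(frame, spec, topology = NULL) {
  a <- cv_group_xyz(frame, spec$group1, topology)
  b <- cv_group_xyz(frame, spec$group2, topology)
  r <- sqrt(cross_dist2(a, b)) / spec$d0
  sum(switching_value(r, spec$n, spec$m))
}

## (1 - r^n)/(1 - r^m), with the factorized singularity-free form when
## m = 2n and the analytic limit n/m at r = 1 otherwise.
switching_value <- function(r, n, m) {
  if (m == 2L * n) return(1 / (1 + r^n))
  out <- (1 - r^n) / (1 - r^m)
  at1 <- abs(r - 1) < 1e-9
  out[at1] <- n / m
  out
}

#' Harmonic wall specification
#'
#' One-sided quadratic restraint `E = (k/2) * delta^2`, where `delta` is
#' the violation depth beyond the wall (zero inside the allowed region).
#'
#' @param variable A CV spec ([distance_inv_spec()] or
#'   [coordination_spec()]).
#' @param lower,upper Wall positions (at least one must be given).
#' @param k Force constant, kcal/mol/unit^2 (default 10).
#' @param name Optional label.
#' @return Object of class `nuc_wall_spec`.
#' @export
harmonic_wall_spec <- function(variable, lower = NULL, upper = NULL, k = 10,
                               name = NULL) {
  if (is.null(lower) && is.null(upper))
    stop("at least one of 'lower'/'upper' must be set")
  stopifnot_scalar_number(k, "k", positive = TRUE)
  structure(list(variable = variable, lower = lower, upper = upper, k = k,
                 name = name),
            class = c("nuc_wall_spec", "nuc_bias_spec"))
}

#' Steered (moving harmonic center) specification
#'
#' The restraint center moves with constant velocity from `from` to `to`
#' over `duration` (ns or frames -- the time axis of the evaluation), then
#' stays clamped at `to`.
#'
#' @param variable A CV spec.
#' @param from,to Start and end center values.
#' @param duration Ramp duration (> 0).
#' @param k Force constant (default 10).
#' @param name Optional label.
#' @return Object of class `nuc_steered_spec`.
#' @export
steered_spec <- function(variable, from, to, duration, k = 10, name = NULL) {
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  structure(list(variable = variable, from = from, to = to,
                 duration = duration, k = k, name = name),
            class = c("nuc_steered_spec", "nuc_bias_spec"))
}

#' Harmonic-wall energy at a CV value
#'
#' @param value CV value(s).
#' @param spec A `nuc_wall_spec`.
#' @return Energy in kcal/mol (vectorized over `value`).
#' @export
wall_energy <- function(value, spec) {
  delta <- numeric(length(value))
  if (!is.null(spec$lower)) delta <- delta + pmax(spec$lower - value, 0)
  if (!is.null(spec$upper)) delta <- delta + pmax(value - spec$upper, 0)
  0.5 * spec$k * delta^2
}

#' Target center of a steered restraint at time t
#'
#' @param t Time(s) on the same axis as `spec$duration` (>= 0).
#' @param spec A `nuc_steered_spec`.
#' @return Target value(s): linear ramp, clamped at the end value.
#' @export
steered_center <- function(t, spec) {
  if (any(t < 0)) stop("negative time")
  f <- pmin(t / spec$duration, 1)
  spec$from + f * (spec$to - spec$from)
}

#' Assemble a named bias protocol
#'
#' @param ... Named `nuc_wall_spec` / `nuc_steered_spec` terms.
#' @param name Protocol name.
#' @return Object of class `nuc_bias_protocol`.
#' @export
bias_protocol <- function(..., name = "protocol") {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1L]]) &&
      !inherits(terms[[1L]], "nuc_bias_spec"))
    terms <- terms[[1L]]
  ok <- vapply(terms, inherits, TRUE, what = "nuc_bias_spec")
  if (!all(ok)) stop("all protocol terms must be wall or steered specs")
  if (length(terms) &&
      (is.null(names(terms)) || any(!nzchar(names(terms)))))
    stop("all protocol terms must be named")
  structure(list(name = name, terms = terms), class = "nuc_bias_protocol")
}

#' @export
print.nuc_bias_protocol <- function(x, ...) {
  cat(sprintf("<nuc_bias_protocol> '%s': %d terms (%s)\n", x$name,
              length(x$terms), paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

## Selections used by the presets (Calpha for protein, P for DNA).
.sel_tails_outer <- function() {
  list(tails = atom_selection(roles = c("H3-A", "H2A-A"), segment = "tail",
                              elety = "CA"),
       outer = atom_selection(roles = "DNA", dna_region = "outer_gyre_3p",
                              elety = "P"))
}

#' Built-in bias protocol presets
#'
#' Two literal protocols:
#' \describe{
#'   \item{`tail_release`}{harmonic walls keeping the minimal H3/H2A-C
#'     tail to outer-gyre distance larger than 12 Angstrom and the
#'     corresponding coordination number equal to 0 (upper wall at 0),
#'     sampling nucleosomes whose tails do not engage the linker-side
#'     DNA.}
#'   \item{`pou_hd_insertion`}{three steered ramps moving the POU_HD
#'     subdomain between the gyres -- its minimal distance to the inner
#'     gyre from 5 to 15 Angstrom, to the outer gyre from 32 to 12, and to
#'     the 3' linker DNA from 58 to 28, applied over 250 ns -- plus guard
#'     walls: tails vs outer gyre kept beyond 30 Angstrom and at zero
#'     coordination, and the inter-gyre minimal distance kept above 20
#'     Angstrom.}
#' }
#' All terms use a force constant of 10 kcal/mol/A^2 and distanceInv
#' exponent n = 100 on C-alpha (protein) / P (DNA) atoms.
#'
#' @param preset `"tail_release"` or `"pou_hd_insertion"`.
#' @return A `nuc_bias_protocol`.
#' @export
bias_protocol_preset <- function(preset = c("tail_release",
                                            "pou_hd_insertion")) {
  preset <- match.arg(preset)
  s <- .sel_tails_outer()
  pou_hd <- atom_selection(roles = "TF", subdomain = "POU_HD", elety = "CA")
  inner <- atom_selection(roles = "DNA", dna_region = "inner_gyre",
                          elety = "P")
  outer <- s$outer
  l3 <- atom_selection(roles = "DNA", dna_region = "linker_3p", elety = "P")

  if (preset == "tail_release") {
    bias_protocol(
      name = "tail_release",
      wall_dmin_tails_outer = harmonic_wall_spec(
        distance_inv_spec(s$tails, outer), lower = 12, k = 10,
        name = "wall_dmin_tails_outer"),
      wall_coord_tails_outer = harmonic_wall_spec(
        coordination_spec(s$tails, outer), upper = 0, k = 10,
        name = "wall_coord_tails_outer"))
  } else {
    bias_protocol(
      name = "pou_hd_insertion",
      steer_pouhd_inner = steered_spec(
        distance_inv_spec(pou_hd, inner), from = 5, to = 15,
        duration = 250, k = 10, name = "steer_pouhd_inner"),
      steer_pouhd_outer = steered_spec(
        distance_inv_spec(pou_hd, outer), from = 32, to = 12,
        duration = 250, k = 10, name = "steer_pouhd_outer"),
      steer_pouhd_l3 = steered_spec(
        distance_inv_spec(pou_hd, l3), from = 58, to = 28,
        duration = 250, k = 10, name = "steer_pouhd_l3"),
      wall_dmin_tails_outer = harmonic_wall_spec(
        distance_inv_spec(s$tails, outer), lower = 30, k = 10,
        name = "wall_dmin_tails_outer"),
      wall_coord_tails_outer = harmonic_wall_spec(
        coordination_spec(s$tails, outer), upper = 0, k = 10,
        name = "wall_coord_tails_outer"),
      wall_dmin_intergyre = harmonic_wall_spec(
        distance_inv_spec(inner, atom_selection(roles = "DNA",
                                                dna_region = "outer_gyres",
                                                elety = "P")),
        lower = 20, k = 10, name = "wall_dmin_intergyre"))
  }
}

eval_cv <- function(frame, variable, topology) {
  if (inherits(variable, "nuc_distance_inv_spec")) {
    distance_inv(frame, variable, topology)
  } else if (inherits(variable, "nuc_coordination_spec")) {
    coordination_number(frame, variable, topology)
  } else stop("unsupported collective-variable kind")
}

#' Evaluate a bias protocol over a trajectory
#'
#' Computes each term's CV value per frame, the instantaneous target (wall
#' bound or steered center), and the restraint energy; flags frames where
#' a term is effectively active (energy > 0). The diagnostic counterpart
#' of verifying that wall biases only act transiently.
#'
#' @param trajectory A `nuc_trajectory`.
#' @param protocol A `nuc_bias_protocol`.
#' @param topology A `nuc_topology`.
#' @param time Optional per-frame times on the steered-duration axis;
#'   default `0:(n_frames-1)`.
#' @param active_tol Energy above which a term counts as effectively
#'   active (kcal/mol; a coordination number is never exactly zero at
#'   finite distance, so a strict > 0 flag would always fire).
#' @return Data frame: `frame`, `term`, `kind`, `value`, `target`,
#'   `energy_kcal_mol`, `active`.
#' @export
evaluate_protocol <- function(trajectory, protocol, topology, time = NULL,
                              active_tol = 1e-3) {
  nf <- n_frames(trajectory)
  if (is.null(time)) time <- seq_len(nf) - 1
  out <- list()
  for (tn in names(protocol$terms)) {
    term <- protocol$terms[[tn]]
    vals <- numeric(nf)
    for (i in seq_len(nf))
      vals[i] <- eval_cv(get_frame(trajectory, i), term$variable, topology)
    if (inherits(term, "nuc_wall_spec")) {
      en <- wall_energy(vals, term)
      tgt <- rep(term$lower %||% term$upper, nf)
      kind <- "wall"
    } else {
      tgt <- steered_center(pmin(time, term$duration), term)
      en <- 0.5 * term$k * (vals - tgt)^2
      kind <- "steered"
    }
    out[[tn]] <- data.frame(frame = seq_len(nf), term = tn, kind = kind,
                            value = vals, target = tgt,
                            energy_kcal_mol = en, active = en > active_tol)
  }
  do.call(rbind, out)
}
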