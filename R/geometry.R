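## Superposition, radius of gyration, dyad frame, breathing angles.

#' Superpose a frame onto a reference
#'
#' Least-squares rigid-body fit (rotation + translation) of `frame` onto
#' `reference` over a selection, by default the C-alpha atoms of the
#' non-tail (globular) histone core — trajectories are conventionally
#' fitted to the histone core, excluding the mobile tails, using the
#' initial structure as reference.
#'
#' @param frame,reference `nuc_frame` objects with identical atom tables.
#' @param topology A `nuc_topology` (used for the default selection).
#' @param selection A `nuc_selection` or atom indices; default histone
#'   globular C-alphas.
#' @return List with `frame` (the fitted `nuc_frame`) and `rmsd`
#'   (post-fit RMSD over the selection, in Angstrom).
#' @export
superpose_to_reference <- function(frame, reference, topology,
                                   selection = NULL) {
  if (is.null(selection))
    selection <- atom_selection(segment = "globular", elety = "CA")
  idx <- resolve_selection(selection, reference, topology)
  if (!length(idx)) stop("empty superposition selection")
  idx_m <- resolve_selection(selection, frame, topology)
  if (length(idx_m) != length(idx))
    stop("superposition selection differs between frame and reference")

  fixed <- as.vector(t(reference$xyz))
  mobile <- as.vector(t(frame$xyz))
  xi <- bio3d::atom2xyz(idx)
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mobile,
                           fixed.inds = xi, mobile.inds = xi)
  fxyz <- matrix(fitted, ncol = 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fxyz[idx, , drop = FALSE] -
                               reference$xyz[idx, , drop = FALSE])^2)))
  out <- frame
  out$xyz <- fxyz
  list(frame = out, rmsd = rmsd)
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i ||r_i - rbar||^2 / sum_i m_i )` with `rbar` the
#' mass-weighted centroid. With `mass_weighted = FALSE` all weights are 1.
#'
#' @param frame A `nuc_frame`.
#' @param selection A `nuc_selection` or atom indices; default: all DNA
#'   heavy atoms.
#' @param topology Needed when `selection` is declarative.
#' @param mass_weighted Use atomic masses as weights (default `TRUE`).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, topology = NULL,
                               mass_weighted = TRUE) {
  if (is.null(selection)) selection <- atom_selection(roles = "DNA")
  idx <- if (is.numeric(selection)) as.integer(selection)
         else resolve_selection(selection, frame, topology)
  if (!length(idx)) stop("empty selection for radius of gyration")
  x <- frame$xyz[idx, , drop = FALSE]
  w <- if (mass_weighted) frame$atoms$mass[idx] else rep(1, length(idx))
  tw <- sum(w)
  if (tw <= 0) stop("zero total mass in selection")
  ctr <- colSums(x * w) / tw
  d2 <- rowSums(sweep(x, 2L, ctr)^2)
  sqrt(sum(w * d2) / tw)
}

## Winding vector of an ordered path: sum of consecutive cross products
## about the centroid. For a superhelix this points along the superhelical
## axis with the winding handedness.
winding_vector <- function(pts) {
  ctr <- colMeans(pts)
  p <- sweep(pts, 2L, ctr)
  n <- nrow(p)
  a <- p[-n, , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  w <- c(sum(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]),
         sum(a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]),
         sum(a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]))
  w
}

## Per-bp representative points: mean of the strand P atoms of each bp
## present in `bp_set`, ordered by bp index.
bp_centers <- function(frame, topology, bp_set, elety = "P") {
  a <- frame$atoms
  sel <- !is.na(a$bp) & a$bp %in% bp_set & a$element != "H"
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  if (!any(sel)) stop("no atoms found for requested base pairs")
  sp <- split(which(sel), a$bp[sel])
  ord <- order(as.integer(names(sp)))
  pts <- t(vapply(sp[ord], function(i) colMeans(frame$xyz[i, , drop = FALSE]),
                  numeric(3L)))
  list(bp = as.integer(names(sp))[ord], pts = pts)
}

#' Build the dyad-anchored coordinate frame
#'
#' Constructs the orthonormal XYZ frame used for breathing angles, once,
#' from a reference structure: the origin sits on the dyad (centroid of the
#' central base pair(s) of the DNA); X is the unit vector from the core-DNA
#' centroid to the origin (the dyad axis); Y = X x n, where n is the
#' best-fit-plane normal of the core phosphates orthogonalized against X
#' and oriented against the winding sense of the DNA path, so that
#' Z = X x Y points along the superhelical axis.
#'
#' @param reference A `nuc_frame` (the fitting reference).
#' @param topology A `nuc_topology`.
#' @return Object of class `nuc_dyad_frame`: list with `origin` and unit
#'   vectors `X`, `Y`, `Z`.
#' @export
build_dyad_frame <- function(reference, topology) {
  n <- topology$n_bp
  dyad_bp <- if (n %% 2L == 0L) c(n %/% 2L, n %/% 2L + 1L) else (n + 1L) %/% 2L
  a <- reference$atoms
  dsel <- !is.na(a$bp) & a$bp %in% dyad_bp & a$element != "H"
  if (!any(dsel)) stop("no atoms at the dyad base pair(s)")
  origin <- colMeans(reference$xyz[dsel, , drop = FALSE])

  rm <- classify_dna_regions(topology)
  core_bp <- rm$bp[rm$region == "core"]
  csel <- !is.na(a$bp) & a$bp %in% core_bp & a$element != "H"
  core_ctr <- colMeans(reference$xyz[csel, , drop = FALSE])
  X <- unit(origin - core_ctr)

  cc <- bp_centers(reference, topology, core_bp)
  pts <- sweep(cc$pts, 2L, colMeans(cc$pts))
  ## remove the linear superhelical rise along the path before the plane
  ## fit: the raw least-squares plane of a helical ramp is tilted by the
  ## pitch, the detrended one is exactly perpendicular to the superhelix
  ## axis on ideal geometry
  k <- seq_len(nrow(pts)) - (nrow(pts) + 1) / 2
  drift <- colSums(pts * k) / sum(k * k)
  sv <- svd(pts - outer(k, drift))
  nrm <- sv$v[, 3L]
  sing <- sv$d
  if (sing[2L] < 1e-6 * max(sing))
    stop("degenerate core-DNA geometry (collinear phosphates)")
  w <- winding_vector(cc$pts)
  if (sum(nrm * w) > 0) nrm <- -nrm   # orient normal against the winding
  nperp <- unit(nrm - sum(nrm * X) * X)
  Y <- unit(c(X[2L] * nperp[3L] - X[3L] * nperp[2L],
              X[3L] * nperp[1L] - X[1L] * nperp[3L],
              X[1L] * nperp[2L] - X[2L] * nperp[1L]))
  Z <- c(X[2L] * Y[3L] - X[3L] * Y[2L],
         X[3L] * Y[1L] - X[1L] * Y[3L],
         X[1L] * Y[2L] - X[2L] * Y[1L])
  structure(list(origin = origin, X = X, Y = Y, Z = Z),
            class = "nuc_dyad_frame")
}

#' @export
print.nuc_dyad_frame <- function(x, ...) {
  cat("<nuc_dyad_frame>\n origin:", sprintf("%.2f", x$origin), "\n")
  invisible(x)
}

#' Direction of a linker DNA arm
#'
#' Best-fit line (principal axis) through the per-bp centroids of the
#' linker DNA, oriented from the core-proximal base pair toward the
#' terminal base pair. By default all heavy atoms contribute to the per-bp
#' centroids (which averages out coordinate noise); `elety = "P"`
#' restricts the fit to the phosphates. Alternatively
#' (`method = "endpoints"`) the normalized vector between the proximal and
#' terminal bp centers.
#'
#' @param frame A `nuc_frame`.
#' @param topology A `nuc_topology`.
#' @param side `"5p"` or `"3p"`.
#' @param method `"fit"` (default) or `"endpoints"`.
#' @param elety Atom names used for the per-bp centroids (`NULL` = all
#'   heavy atoms).
#' @return Unit 3-vector.
#' @export
linker_vector <- function(frame, topology, side = c("5p", "3p"),
                          method = c("fit", "endpoints"), elety = NULL) {
  side <- match.arg(side)
  method <- match.arg(method)
  rm <- classify_dna_regions(topology)
  reg <- paste0("linker_", side)
  bps <- rm$bp[rm$region == reg]
  if (length(bps) < 3L)
    stop("linker too short for a stable direction fit (need >= 3 bp)")
  cc <- bp_centers(frame, topology, bps, elety = elety)
  ## outward order: 5' linker runs terminal->core in bp index, 3' runs
  ## core->terminal
  ord <- if (side == "5p") rev(seq_len(nrow(cc$pts))) else seq_len(nrow(cc$pts))
  pts <- cc$pts[ord, , drop = FALSE]
  outward <- pts[nrow(pts), ] - pts[1L, ]
  if (sqrt(sum(outward^2)) < 1e-9)
    stop("degenerate linker geometry (coincident points)")
  if (method == "endpoints") return(unit(outward))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  v <- sv$v[, 1L]
  if (sum(v * outward) < 0) v <- -v
  unit(v)
}

#' Breathing angles of both linker arms
#'
#' For each linker direction v (from [linker_vector()]), gamma1 is the
#' signed angle in the XZ plane from the Z axis to the projection of v
#' (positive rotation about +Y), and gamma2 the signed angle in the XY
#' plane from the Y axis to the projection (positive rotation about +Z).
#' Degrees. A projection with near-zero norm is flagged `NA` (undefined).
#'
#' @param frame A `nuc_frame`, superposed to the reference that produced
#'   `dyad_frame`.
#' @param dyad_frame A `nuc_dyad_frame`.
#' @param topology A `nuc_topology`.
#' @param method Passed to [linker_vector()].
#' @param flip Named numeric `c(gamma1 = 1, gamma2 = 1)`; set an entry to
#'   -1 to flip that sign convention.
#' @return One-row data frame with `gamma1_5p`, `gamma2_5p`, `gamma1_3p`,
#'   `gamma2_3p` (degrees).
#' @export
breathing_angles <- function(frame, dyad_frame, topology,
                             method = "fit", flip = c(gamma1 = 1, gamma2 = 1)) {
  one <- function(side) {
    v <- linker_vector(frame, topology, side, method)
    gamma_of_vector(v, dyad_frame, flip)
  }
  g5 <- one("5p"); g3 <- one("3p")
  data.frame(gamma1_5p = g5[1L], gamma2_5p = g5[2L],
             gamma1_3p = g3[1L], gamma2_3p = g3[2L])
}

#' Projection angles of a direction vector in a dyad frame
#'
#' @param v Unit 3-vector (world coordinates).
#' @param dyad_frame A `nuc_dyad_frame`.
#' @param flip Sign convention, see [breathing_angles()].
#' @return Numeric `c(gamma1, gamma2)` in degrees (`NA` where the
#'   projection norm is near zero).
#' @export
gamma_of_vector <- function(v, dyad_frame, flip = c(gamma1 = 1, gamma2 = 1)) {
  vx <- sum(v * dyad_frame$X)
  vy <- sum(v * dyad_frame$Y)
  vz <- sum(v * dyad_frame$Z)
  g1 <- if (vx^2 + vz^2 < 1e-12) NA_real_ else deg(atan2(vx, vz)) * flip[["gamma1"]]
  g2 <- if (vx^2 + vy^2 < 1e-12) NA_real_ else deg(atan2(vx, vy)) * flip[["gamma2"]]
  c(gamma1 = g1, gamma2 = g2)
}

#' Exact minimal distance between two atom groups
#'
#' @param frame A `nuc_frame`.
#' @param groupA,groupB Selections or atom indices.
#' @param topology Needed for declarative selections.
#' @return Minimal pairwise Euclidean distance (Angstrom).
#' @export
min_group_distance <- function(frame, groupA, groupB, topology = NULL) {
  ia <- resolve_selection(groupA, frame, topology)
  ib <- resolve_selection(groupB, frame, topology)
  if (!length(ia) || !length(ib)) stop("empty group")
  sqrt(min(cross_dist2(frame$xyz[ia, , drop = FALSE],
                       frame$xyz[ib, , drop = FALSE])))
}

#' Per-frame geometry series of a trajectory
#'
#' Fits every frame to the reference over the histone globular core, then
#' reports the mass-weighted DNA radius of gyration, the four breathing
#' angles and the minimal inner/outer-gyre heavy-atom distance.
#'
#' @param trajectory A `nuc_trajectory`.
#' @param topology A `nuc_topology`.
#' @param reference A `nuc_frame`; default: first frame of the trajectory.
#' @param fit Superpose each frame onto the reference first (default
#'   `TRUE`; disable for pre-fitted trajectories).
#' @param method Linker-direction method, see [linker_vector()].
#' @return Data frame with columns `frame`, `time_ns`, `Rg_A`,
#'   `gamma1_5p_deg`, `gamma2_5p_deg`, `gamma1_3p_deg`, `gamma2_3p_deg`,
#'   `intergyre_min_A`.
#' @export
analyze_trajectory <- function(trajectory, topology, reference = NULL,
                               fit = TRUE, method = "fit") {
  if (is.null(reference)) reference <- get_frame(trajectory, 1L)
  dyad <- build_dyad_frame(reference, topology)
  dna <- atom_selection(roles = "DNA")
  ## inter-gyre separation over the phosphates, matching the P-atom
  ## convention of the DNA collective-variable groups
  inner <- atom_selection(roles = "DNA", dna_region = "inner_gyre",
                          elety = "P")
  outer <- atom_selection(roles = "DNA", dna_region = "outer_gyres",
                          elety = "P")
  ref_inner <- resolve_selection(inner, reference, topology)
  ref_outer <- resolve_selection(outer, reference, topology)
  ref_dna <- resolve_selection(dna, reference, topology)

  nf <- n_frames(trajectory)
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(trajectory, i)
    if (fit) fr <- superpose_to_reference(fr, reference, topology)$frame
    g <- breathing_angles(fr, dyad, topology, method = method)
    out[[i]] <- data.frame(
      frame = i,
      time_ns = fr$time_ns,
      Rg_A = radius_of_gyration(fr, ref_dna),
      gamma1_5p_deg = g$gamma1_5p, gamma2_5p_deg = g$gamma2_5p,
      gamma1_3p_deg = g$gamma1_3p, gamma2_3p_deg = g$gamma2_3p,
      intergyre_min_A = min_group_distance(fr, ref_inner, ref_outer))
  }
  do.call(rbind, out)
}
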