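## Synthetic nucleosome generator: idealized superhelical DNA, pseudo-
## histone core with tails, optional two-domain pseudo-TF, and breathing
## trajectories with exact ground truth.

#' Parameters for the synthetic nucleosome generator
#'
#' Defaults describe a canonical 168-bp nucleosome: 146 bp of core DNA on
#' a left-handed-like superhelical ramp of radius 41.9 Angstrom, pitch
#' 25.9 Angstrom and 1.65 turns, with 11-bp straight B-DNA linker arms
#' (rise 3.4 Angstrom/bp) at each end. Each nucleotide carries three
#' pseudo-atoms (P and C1' backbone, an N1 base proxy) on a twisted
#' two-strand lattice, enough to exercise the base/backbone partition and
#' mass-weighted observables. Pseudo-histones are a rigid random cluster
#' of C-alpha beads at the superhelix center plus tail walks; a pseudo-TF
#' with POU_S / POU_HD subdomains can be attached. All randomness flows
#' from `seed`; equal seeds give bit-identical output.
#'
#' @param n_bp Total base pairs (default 168).
#' @param core Core (wrapped) base pairs (default 146).
#' @param outer Outer-gyre size per end in bp (default 40).
#' @param superhelix_radius,superhelix_pitch,wrap_turns Superhelical ramp
#'   geometry (Angstrom, Angstrom, turns).
#' @param linker_rise Rise per bp along the straight linker arms (Angstrom).
#' @param twist_deg Duplex twist per bp (degrees).
#' @param p_radius,c1p_radius,base_radius Radial distance of the P, C1'
#'   and base-proxy atoms from the duplex axis (Angstrom).
#' @param species Histone tail preset (`"human"` or `"drosophila"`).
#' @param histone_ball_radius Radius of the pseudo-histone core cluster.
#' @param tail_step Tail bead step length (Angstrom).
#' @param tail_mode `"wrapped"` (H3/H2A-C tails of copy A contact the 3'
#'   outer gyre) or `"released"` (all tails away from DNA).
#' @param tail_release_frame Optional frame index at which wrapped tails
#'   detach during a trajectory.
#' @param tf_mode `"none"`, `"free"`, `"inner"` or `"bridging"` placement
#'   of the POU_HD pseudo-domain (POU_S is placed on the site whenever a
#'   TF is present).
#' @param tf_site Base-pair window (length-2 vector) of the POU_S site.
#' @param tf_attach `"bases"` or `"backbone"`: whether POU_S interface
#'   atoms approach base or backbone atoms of the site.
#' @param frames Number of trajectory frames.
#' @param opening List describing the breathing schedule: `arm` (`"3p"`,
#'   `"5p"` or `"both"`), `dgamma1` and `dgamma2` (length-2 start/end
#'   opening magnitudes in degrees, applied in the Rg-increasing sense).
#' @param noise_sd Gaussian coordinate noise per frame (Angstrom).
#' @param seed Integer seed for all randomness.
#' @return Object of class `nuc_synth_params`.
#' @export
synthetic_params <- function(n_bp = 168L, core = 146L, outer = 40L,
                             superhelix_radius = 41.9,
                             superhelix_pitch = 25.9,
                             wrap_turns = 1.65,
                             linker_rise = 3.4, twist_deg = 36,
                             p_radius = 8.9, c1p_radius = 5.9,
                             base_radius = 2.8,
                             species = "human",
                             histone_ball_radius = 24,
                             tail_step = 3.8,
                             tail_mode = c("wrapped", "released"),
                             tail_release_frame = NULL,
                             tf_mode = c("none", "free", "inner", "bridging"),
                             tf_site = c(60L, 68L),
                             tf_attach = c("bases", "backbone"),
                             frames = 1L,
                             opening = list(arm = "3p", dgamma1 = c(0, 0),
                                            dgamma2 = c(0, 0)),
                             noise_sd = 0, seed = 1L) {
  p <- list(n_bp = as.integer(n_bp), core = as.integer(core),
            outer = as.integer(outer),
            superhelix_radius = superhelix_radius,
            superhelix_pitch = superhelix_pitch,
            wrap_turns = wrap_turns, linker_rise = linker_rise,
            twist_deg = twist_deg, p_radius = p_radius,
            c1p_radius = c1p_radius, base_radius = base_radius,
            species = species,
            histone_ball_radius = histone_ball_radius,
            tail_step = tail_step, tail_mode = match.arg(tail_mode),
            tail_release_frame = tail_release_frame,
            tf_mode = match.arg(tf_mode),
            tf_site = as.integer(tf_site),
            tf_attach = match.arg(tf_attach),
            frames = as.integer(frames), opening = opening,
            noise_sd = noise_sd, seed = as.integer(seed))
  for (nm in c("superhelix_radius", "superhelix_pitch", "wrap_turns",
               "linker_rise", "p_radius", "c1p_radius", "base_radius",
               "histone_ball_radius", "tail_step"))
    stopifnot_scalar_number(p[[nm]], nm, positive = TRUE)
  if (p$core > p$n_bp) stop("core exceeds n_bp")
  n_linker <- p$n_bp - p$core
  if (p$tf_mode != "none" &&
      (p$tf_site[1L] < 1L || p$tf_site[2L] > p$n_bp))
    stop("tf_site window outside 1..n_bp")
  if (p$frames < 1L) stop("frames must be >= 1")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(p, class = "nuc_synth_params")
}

## --- DNA geometry ------------------------------------------------------

## Per-bp centers and local duplex frames (tangent t, perpendiculars e1,
## e2) for the wrapped core and straight linker arms.
superhelix_geometry <- function(p) {
  n <- p$n_bp
  rem <- n - p$core
  l5 <- rem %/% 2L
  core_bp <- seq.int(l5 + 1L, l5 + p$core)
  bp_mid <- l5 + (p$core + 1) / 2
  dtheta <- p$wrap_turns * 2 * pi / (p$core - 1)
  cz <- p$superhelix_pitch / (2 * pi)
  R <- p$superhelix_radius

  centers <- matrix(NA_real_, n, 3L)
  tang <- matrix(NA_real_, n, 3L)
  e1 <- matrix(NA_real_, n, 3L)
  for (b in core_bp) {
    th <- (b - bp_mid) * dtheta
    centers[b, ] <- c(R * cos(th), R * sin(th), cz * th)
    tg <- unit(c(-R * sin(th), R * cos(th), cz))
    tang[b, ] <- tg
    rad_out <- c(cos(th), sin(th), 0)
    e1[b, ] <- unit(rad_out - sum(rad_out * tg) * tg)
  }
  ## straight arms continue along the terminal tangents
  cs <- core_bp[1L]; ce <- core_bp[length(core_bp)]
  if (l5 > 0L) for (i in seq_len(l5)) {
    b <- cs - i
    centers[b, ] <- centers[cs, ] - i * p$linker_rise * tang[cs, ]
    tang[b, ] <- tang[cs, ]
    e1[b, ] <- e1[cs, ]
  }
  l3 <- rem - l5
  if (l3 > 0L) for (i in seq_len(l3)) {
    b <- ce + i
    centers[b, ] <- centers[ce, ] + i * p$linker_rise * tang[ce, ]
    tang[b, ] <- tang[ce, ]
    e1[b, ] <- e1[ce, ]
  }
  e2 <- matrix(NA_real_, n, 3L)
  for (b in seq_len(n)) {
    tg <- tang[b, ]
    e2[b, ] <- c(tg[2L] * e1[b, 3L] - tg[3L] * e1[b, 2L],
                 tg[3L] * e1[b, 1L] - tg[1L] * e1[b, 3L],
                 tg[1L] * e1[b, 2L] - tg[2L] * e1[b, 1L])
  }
  list(centers = centers, tang = tang, e1 = e1, e2 = e2,
       core_bp = core_bp, l5 = l5, l3 = l3,
       arm5_bp = if (l5) seq_len(l5) else integer(0),
       arm3_bp = if (l3) seq.int(ce + 1L, n) else integer(0),
       pivot5 = centers[cs, ], pivot3 = centers[ce, ],
       v5 = -tang[cs, ], v3 = tang[ce, ])
}

## strand atom position: angle psi on the duplex circle of base pair b
strand_dir <- function(geo, b, psi) {
  cos(psi) * geo$e1[b, ] + sin(psi) * geo$e2[b, ]
}

## Pseudo-nucleotide: nine heavy atoms (six backbone, three base) at
## fixed radii from the duplex axis and small twist-phase offsets, so
## that per-bp noise averaging and the base/backbone split behave like
## real DNA. The two strands sit at antipodal phases, which keeps per-bp
## centroids exactly on the duplex axis.
dna_atom_types <- function(p) {
  data.frame(
    elety = c("P", "OP1", "OP2", "O5'", "C4'", "C1'", "N1", "C2", "C4"),
    element = c("P", "O", "O", "O", "C", "C", "N", "C", "C"),
    mass = c(30.973762, 15.999, 15.999, 15.999, 12.011, 12.011,
             14.007, 12.011, 12.011),
    radius = c(p$p_radius, p$p_radius + 0.9, p$p_radius + 0.9,
               p$p_radius - 0.6, p$c1p_radius + 1.0, p$c1p_radius,
               p$base_radius, p$base_radius - 0.8, p$base_radius + 0.6),
    dpsi = c(0, 0.35, -0.35, 0.15, 0.1, 0, 0, 0.6, -0.6),
    stringsAsFactors = FALSE)
}

build_dna <- function(p, geo) {
  n <- p$n_bp
  ty <- dna_atom_types(p)
  k <- nrow(ty)
  atoms <- list(); coords <- list()
  for (strand in c("I", "J")) {
    res <- rep(seq_len(n), each = k)
    b <- if (strand == "I") res else n + 1L - res
    phase <- if (strand == "I") 0 else pi
    psi <- rad(p$twist_deg) * (b - 1L) + phase + ty$dpsi[rep(seq_len(k), n)]
    r <- ty$radius[rep(seq_len(k), n)]
    dirv <- cos(psi) * geo$e1[b, , drop = FALSE] +
      sin(psi) * geo$e2[b, , drop = FALSE]
    coords[[strand]] <- geo$centers[b, , drop = FALSE] + r * dirv
    atoms[[strand]] <- data.frame(
      elety = ty$elety[rep(seq_len(k), n)],
      resid = if (strand == "I") "DA" else "DT",
      chain = strand, resno = res,
      element = ty$element[rep(seq_len(k), n)],
      mass = ty$mass[rep(seq_len(k), n)],
      stringsAsFactors = FALSE)
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, coords))
}

## --- histones ----------------------------------------------------------

histone_layout <- function(species) {
  tl <- tail_preset(species)
  len <- c(H3 = 135L, H4 = 102L,
           H2A = max(tl$H2A) , H2B = max(tl$H2B) + 92L)
  list(tails = tl, lengths = len)
}

ball_points <- function(n, radius, center = c(0, 0, 0), avoid = NULL,
                        min_dist = 6) {
  pts <- matrix(NA_real_, n, 3L)
  i <- 1L
  tries <- 0L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("cannot place cluster points away from excluded region")
    u <- stats::runif(3L, -1, 1) * radius
    if (sum(u^2) > radius^2) next
    cand <- center + u
    if (!is.null(avoid) &&
        min((avoid[, 1L] - cand[1L])^2 + (avoid[, 2L] - cand[2L])^2 +
              (avoid[, 3L] - cand[3L])^2) < min_dist^2) next
    pts[i, ] <- cand
    i <- i + 1L
  }
  pts
}

## biased outward walk along +/- z, mildly self-avoiding
tail_walk <- function(n_beads, start, zsign, step) {
  pts <- matrix(NA_real_, n_beads, 3L)
  cur <- start
  for (i in seq_len(n_beads)) {
    for (try in 1:50) {
      d <- unit(c(stats::rnorm(2L, 0, 0.4), zsign))
      cand <- cur + step * d
      if (i == 1L || min(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE],
                                       2L, cand)^2)) > 4)
        break
    }
    pts[i, ] <- cand
    cur <- cand
  }
  pts
}

## wrapped tail: beads hugging the radially-outward P atoms of given bps
wrapped_tail_points <- function(p, geo, n_beads, bps, jitter = 0.15) {
  pts <- matrix(NA_real_, n_beads, 3L)
  nbp <- length(bps)
  for (i in seq_len(n_beads)) {
    b <- bps[((i - 1L) %% nbp) + 1L]
    psi <- rad(p$twist_deg) * (b - 1L)
    dirv <- strand_dir(geo, b, psi)
    rad_out <- unit(c(geo$centers[b, 1L], geo$centers[b, 2L], 0))
    if (sum(dirv * rad_out) < 0) dirv <- -dirv   # take the outward strand
    pts[i, ] <- geo$centers[b, ] + (p$p_radius + 3.5) * dirv +
      stats::rnorm(3L, 0, jitter)
  }
  pts
}

build_histones <- function(p, geo) {
  lay <- histone_layout(p$species)
  chains <- c(A = "H3-A", B = "H4-A", C = "H2A-A", D = "H2B-A",
              E = "H3-B", F = "H4-B", G = "H2A-B", H = "H2B-B")
  rm3 <- geo$arm3_bp
  ## bps used by wrapped tails: core part of the 3' outer gyre, away from
  ## the mobile linker junction
  wrap_bps <- seq.int(p$n_bp - p$outer + 1L, p$n_bp - geo$l3 - 7L)
  atoms <- list(); xyz <- list()
  ci <- 0L
  for (ch in names(chains)) {
    ci <- ci + 1L
    role <- chains[[ch]]
    ht <- role_type(role)
    lth <- lay$lengths[[ht]]
    tl <- lay$tails[[ht]]
    glob <- setdiff(seq_len(lth), tl)
    gx <- ball_points(length(glob), p$histone_ball_radius)
    zsign <- if (ci %% 2L) 1 else -1
    a0 <- 2 * pi * ci / 8
    ## split tail residues into contiguous runs (N-terminal; H2A also C)
    runs <- split(tl, cumsum(c(1L, diff(tl) != 1L)))
    tx <- matrix(NA_real_, 0L, 3L)
    txr <- integer(0)
    for (rn in runs) {
      cterm <- rn[1L] > 100L
      wrapped <- p$tail_mode == "wrapped" && role %in% c("H3-A", "H2A-A") &&
        (ht == "H3" || cterm)
      if (wrapped) {
        pts <- wrapped_tail_points(p, geo, length(rn), wrap_bps)
      } else {
        start <- c(8 * cos(a0), 8 * sin(a0),
                   zsign * (p$histone_ball_radius + 4))
        pts <- tail_walk(length(rn), start, zsign, p$tail_step)
      }
      tx <- rbind(tx, pts)
      txr <- c(txr, rn)
    }
    resno <- c(txr, glob)
    pos <- rbind(tx, gx)
    atoms[[ch]] <- data.frame(
      elety = "CA", resid = "ALA", chain = ch, resno = resno,
      element = "C", mass = 12.011, stringsAsFactors = FALSE)
    xyz[[ch]] <- pos
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz),
       chains = chains, wrap_bps = wrap_bps)
}

## --- pseudo-TF ---------------------------------------------------------

build_tf <- function(p, geo, dna) {
  site <- seq.int(p$tf_site[1L], p$tf_site[2L])
  nsite <- length(site)
  pou_s <- 1:75; linker <- 76:89; pou_hd <- 90:145
  pos <- matrix(NA_real_, 145L, 3L)

  ## POU_S: interface residues approach the site window
  iface_s <- pou_s[seq_len(nsite)]
  for (k in seq_along(iface_s)) {
    b <- site[k]
    psi <- rad(p$twist_deg) * (b - 1L)
    dirv <- strand_dir(geo, b, psi)
    if (p$tf_attach == "bases") {
      anchor <- geo$centers[b, ] + p$base_radius * dirv
      pos[iface_s[k], ] <- anchor + 4.0 * unit(dirv + geo$tang[b, ])
    } else {
      anchor <- geo$centers[b, ] + p$p_radius * dirv
      pos[iface_s[k], ] <- anchor + 4.0 * dirv
    }
  }
  anchor_s <- colMeans(pos[iface_s, , drop = FALSE])
  rad_out <- unit(c(anchor_s[1L], anchor_s[2L], 0))
  rest_s <- setdiff(pou_s, iface_s)
  pos[rest_s, ] <- ball_points(length(rest_s), 7,
                               anchor_s + 14 * rad_out,
                               avoid = dna$xyz)

  ## POU_HD placement per mode
  hd_anchor <- switch(
    p$tf_mode,
    free = c(0, 0, -70),
    inner = {
      b <- max(1L, p$tf_site[1L] - 10L)
      psi <- rad(p$twist_deg) * (b - 1L)
      geo$centers[b, ] + (p$p_radius + 4.0) *
        strand_dir(geo, b, psi)
    },
    bridging = NULL,
    c(0, 0, -70))
  iface_hd <- pou_hd[1:8]
  if (identical(p$tf_mode, "bridging")) {
    ## midpoints of close inner-gyre / outer-gyre phosphate pairs
    a <- dna$atoms
    pa <- a$elety == "P"
    bp_of <- ifelse(a$chain == "I", a$resno, p$n_bp + 1L - a$resno)
    outer3 <- pa & bp_of > p$n_bp - p$outer
    inner <- pa & bp_of > p$outer & bp_of <= p$n_bp - p$outer
    d2 <- cross_dist2(dna$xyz[outer3, , drop = FALSE],
                      dna$xyz[inner, , drop = FALSE])
    ## pairs whose midpoint contacts both phosphates without overlapping
    ## either (gap 6-9 A)
    hit <- which(d2 > 36 & d2 < 81, arr.ind = TRUE)
    if (!nrow(hit)) stop("no bridging geometry available")
    npick <- min(length(iface_hd), nrow(hit))
    pick <- hit[round(seq(1L, nrow(hit), length.out = npick)), ,
                drop = FALSE]
    mids <- (dna$xyz[outer3, , drop = FALSE][pick[, 1L], , drop = FALSE] +
               dna$xyz[inner, , drop = FALSE][pick[, 2L], , drop = FALSE]) / 2
    pos[iface_hd[seq_len(npick)], ] <- mids
    if (npick < length(iface_hd)) {
      extra <- iface_hd[(npick + 1L):length(iface_hd)]
      pos[extra, ] <- mids[rep(seq_len(npick),
                               length.out = length(extra)), , drop = FALSE] +
        matrix(stats::rnorm(3L * length(extra), 0, 0.4), ncol = 3L)
    }
    hd_anchor <- colMeans(mids)
  } else if (p$tf_mode == "inner") {
    for (k in seq_along(iface_hd)) {
      b <- max(1L, p$tf_site[1L] - 10L) + (k - 1L)
      psi <- rad(p$twist_deg) * (b - 1L)
      dirv <- strand_dir(geo, b, psi)
      rad_out <- unit(c(geo$centers[b, 1L], geo$centers[b, 2L], 0))
      if (sum(dirv * rad_out) < 0) dirv <- -dirv
      pos[iface_hd[k], ] <- geo$centers[b, ] + (p$p_radius + 4.0) * dirv
    }
    hd_anchor <- colMeans(pos[iface_hd, , drop = FALSE])
  } else {
    pos[iface_hd, ] <- ball_points(8L, 4, hd_anchor)
  }
  rest_hd <- setdiff(pou_hd, iface_hd)
  ## rest of the domain: compact cluster escaping radially (or axially
  ## for the free mode) from the interface anchor
  ref_pt <- pos[iface_hd[1L], ]
  cloud_ctr <- if (p$tf_mode %in% c("inner", "bridging")) {
    ref_pt + 20 * unit(c(ref_pt[1L], ref_pt[2L], 0))
  } else hd_anchor + c(0, 0, -14)
  pos[rest_hd, ] <- ball_points(length(rest_hd), 6, cloud_ctr,
                                avoid = dna$xyz)

  ## interdomain linker: straight interpolation with jitter
  cs <- colMeans(pos[pou_s, , drop = FALSE])
  ch <- colMeans(pos[pou_hd, , drop = FALSE])
  f <- seq_along(linker) / (length(linker) + 1)
  pos[linker, ] <- t(vapply(f, function(u) cs + u * (ch - cs), numeric(3L))) +
    matrix(stats::rnorm(3L * length(linker), 0, 0.5), ncol = 3L)

  atoms <- data.frame(elety = "CA", resid = "ALA", chain = "T",
                      resno = 1:145, element = "C", mass = 12.011,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = pos)
}

## independent pair counter used for ground-truth bookkeeping
truth_pair_count <- function(xa, xb, cutoff = 4.5) {
  if (!nrow(xa) || !nrow(xb)) return(0L)
  n <- 0L
  c2 <- cutoff^2
  for (i in seq_len(nrow(xa))) {
    dd <- (xb[, 1L] - xa[i, 1L])^2 + (xb[, 2L] - xa[i, 2L])^2 +
      (xb[, 3L] - xa[i, 3L])^2
    n <- n + sum(dd < c2)
  }
  n
}

synth_config <- function(p, with_tf) {
  chains <- list(I = "DNA-I", J = "DNA-J", A = "H3-A", B = "H4-A",
                 C = "H2A-A", D = "H2B-A", E = "H3-B", F = "H4-B",
                 G = "H2A-B", H = "H2B-B")
  if (with_tf) chains$T <- "TF"
  cfg <- list(n_bp = p$n_bp, species = p$species, chains = chains,
              regions = list(core = p$core, outer_gyre = p$outer))
  if (with_tf)
    cfg$tf_subdomains <- list(POU_S = c(1L, 75L), linker = c(76L, 89L),
                              POU_HD = c(90L, 145L))
  cfg
}

#' Build an idealized nucleosome with ground truth
#'
#' @param params A `nuc_synth_params`.
#' @return List of class `nuc_synthetic` with elements `frame`
#'   (`nuc_frame`), `topology` (`nuc_topology`), `config` (the matching
#'   region-configuration list), and `truth` (closed-state breathing
#'   angles per arm, tail and TF contact counts, the dyad frame, and the
#'   generator's arm axes and pivots).
#' @export
build_ideal_nucleosome <- function(params) {
  stopifnot(inherits(params, "nuc_synth_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)

  geo <- superhelix_geometry(params)
  dna <- build_dna(params, geo)
  his <- build_histones(params, geo)
  with_tf <- params$tf_mode != "none"
  tf <- if (with_tf) build_tf(params, geo, dna) else NULL

  atoms <- rbind(dna$atoms, his$atoms, if (with_tf) tf$atoms)
  xyz <- rbind(dna$xyz, his$xyz, if (with_tf) tf$xyz)
  atoms$eleno <- seq_len(nrow(atoms))

  cfg <- synth_config(params, with_tf)
  topo <- build_topology(cfg)
  atoms <- bind_topology(atoms, topo)
  frame <- new_frame(atoms, xyz)

  if (with_tf) {
    glob <- frame$atoms$role != "TF" &
      role_type(frame$atoms$role) %in% c("H3", "H4", "H2A", "H2B") &
      !frame$atoms$tail
    dmin <- sqrt(min(cross_dist2(tf$xyz, xyz[glob, , drop = FALSE])))
    if (dmin < 2)
      stop("pseudo-TF placement collides with the histone core cluster")
  }

  truth <- synth_truth(frame, topo, params, geo)
  structure(list(frame = frame, topology = topo, config = cfg,
                 truth = truth, geo = geo, params = params),
            class = "nuc_synthetic")
}

synth_truth <- function(frame, topo, params, geo) {
  dyad <- build_dyad_frame(frame, topo)
  g5 <- gamma_of_vector(geo$v5, dyad)
  g3 <- gamma_of_vector(geo$v3, dyad)
  a <- frame$atoms
  truth <- list(
    dyad_frame = dyad,
    arm_axes = list(`5p` = geo$v5, `3p` = geo$v3),
    pivots = list(`5p` = geo$pivot5, `3p` = geo$pivot3),
    gamma = data.frame(arm = c("5p", "3p"),
                       gamma1 = c(g5[["gamma1"]], g3[["gamma1"]]),
                       gamma2 = c(g5[["gamma2"]], g3[["gamma2"]])))

  rm <- classify_dna_regions(topo)
  outer_bp <- rm$bp[rm$gyre != "inner_gyre"]
  heavy <- a$element != "H"
  outer_idx <- which(heavy & !is.na(a$bp) & a$bp %in% outer_bp)
  tail_counts <- list()
  for (r in c("H3-A", "H2A-A")) {
    ti <- which(a$role == r & a$tail)
    tail_counts[[r]] <- truth_pair_count(frame$xyz[ti, , drop = FALSE],
                                         frame$xyz[outer_idx, , drop = FALSE])
  }
  truth$tail_outer_counts <- tail_counts

  if (!is.null(topo$tf_subdomains)) {
    rows <- list()
    for (sd in c("POU_S", "POU_HD")) {
      si <- which(heavy & !is.na(a$subdomain) & a$subdomain == sd)
      for (part in c("base", "backbone")) {
        for (gy in c("inner", "outer", "all")) {
          keep_bp <- switch(gy,
                            inner = rm$bp[rm$gyre == "inner_gyre"],
                            outer = outer_bp,
                            all = rm$bp)
          di <- which(heavy & !is.na(a$bp) & a$bp %in% keep_bp &
                        a$dna_part == part)
          rows[[length(rows) + 1L]] <- data.frame(
            subdomain = sd, dna_part = part, gyre = gy,
            count = truth_pair_count(frame$xyz[si, , drop = FALSE],
                                     frame$xyz[di, , drop = FALSE]))
        }
      }
    }
    truth$tf_contacts <- do.call(rbind, rows)
  }
  truth
}

#' Attach a two-domain pseudo-TF to a synthetic nucleosome
#'
#' Rebuilds the given synthetic nucleosome with the requested pseudo-TF
#' placement (same seed, so the DNA and histones are identical) and
#' refreshed ground truth.
#'
#' @param nuc A `nuc_synthetic` (from [build_ideal_nucleosome()]).
#' @param tf_mode,tf_site,tf_attach See [synthetic_params()].
#' @return A new `nuc_synthetic` including the TF chain.
#' @export
place_pseudo_tf <- function(nuc, tf_mode = "bridging",
                            tf_site = nuc$params$tf_site,
                            tf_attach = nuc$params$tf_attach) {
  stopifnot(inherits(nuc, "nuc_synthetic"))
  p <- nuc$params
  p$tf_mode <- match.arg(tf_mode, c("free", "inner", "bridging"))
  p$tf_site <- as.integer(tf_site)
  p$tf_attach <- match.arg(tf_attach, c("bases", "backbone"))
  build_ideal_nucleosome(p)
}

## absolute-gamma construction of an arm direction: the two projection
## angles jointly determine the axis on the +X half-space
gamma_to_vector <- function(gamma1, gamma2, dyad) {
  g1 <- rad(gamma1); g2 <- rad(gamma2)
  if (sin(g1) <= 1e-9 || sin(g2) <= 1e-9)
    stop("absolute (gamma1, gamma2) targets must lie in (0, 180) degrees")
  v <- c(1, 1 / tan(g2), 1 / tan(g1))
  unit(v[1L] * dyad$X + v[2L] * dyad$Y + v[3L] * dyad$Z)
}

## Rg-increasing sign of a gamma1 perturbation for one arm
opening_sign <- function(nuc, arm) {
  base <- nuc$truth$gamma
  g <- base[base$arm == arm, ]
  rg <- function(dg) {
    fr <- rotate_arm(nuc, arm, g$gamma1 + dg, g$gamma2)
    radius_of_gyration(fr, atom_selection(roles = "DNA"), nuc$topology)
  }
  if (rg(5) >= rg(-5)) 1 else -1
}

## rigidly rotate one linker arm to the absolute (gamma1, gamma2) target
rotate_arm <- function(nuc, arm, gamma1, gamma2, frame = NULL) {
  fr <- frame %||% nuc$frame
  geo <- nuc$geo
  v0 <- nuc$truth$arm_axes[[arm]]
  pivot <- nuc$truth$pivots[[arm]]
  vt <- gamma_to_vector(gamma1, gamma2, nuc$truth$dyad_frame)
  R <- rotation_between(v0, vt)
  bps <- if (arm == "5p") geo$arm5_bp else geo$arm3_bp
  idx <- which(!is.na(fr$atoms$bp) & fr$atoms$bp %in% bps)
  x <- sweep(fr$xyz[idx, , drop = FALSE], 2L, pivot)
  fr$xyz[idx, ] <- sweep(x %*% t(R), 2L, pivot, "+")
  fr
}

#' Generate a synthetic breathing trajectory with ground truth
#'
#' Frames realize the opening schedule by rigidly rotating the linker
#' arm(s) so that their axes hit per-frame absolute (gamma1, gamma2)
#' targets; the schedule is specified as opening magnitudes relative to
#' the closed baseline, applied in the Rg-increasing sense, linearly
#' interpolated across frames. Optional Gaussian coordinate noise and a
#' tail-release event are superimposed. Ground truth records the exact
#' per-frame target angles, the per-frame wrapped-tail vs outer-gyre
#' contact counts, and the release frame.
#'
#' @param params A `nuc_synth_params` (`frames`, `opening`, `noise_sd`,
#'   `tail_release_frame` drive the trajectory).
#' @return List of class `nuc_synth_trajectory`: `trajectory`
#'   (`nuc_trajectory`), `topology`, `reference` (the noise-free closed
#'   frame), `truth` (per-frame data frame `frame`, `arm`, `gamma1`,
#'   `gamma2`; `tail_series`; `release_frame`), plus the underlying
#'   `nuc_synthetic`.
#' @export
generate_breathing_trajectory <- function(params) {
  nuc <- build_ideal_nucleosome(params)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed + 1L)

  nf <- params$frames
  op <- params$opening
  arms <- switch(op$arm %||% "3p",
                 both = c("5p", "3p"), `5p` = "5p", `3p` = "3p",
                 stop("opening$arm must be '5p', '3p' or 'both'"))
  ramp <- function(rng) {
    if (nf == 1L) rng[1L] else seq(rng[1L], rng[2L], length.out = nf)
  }
  d1 <- ramp(op$dgamma1 %||% c(0, 0))
  d2 <- ramp(op$dgamma2 %||% c(0, 0))

  signs <- vapply(arms, function(a) opening_sign(nuc, a), numeric(1L))
  base <- nuc$truth$gamma

  ## released tail coordinates, precomputed once (used after the event)
  released <- NULL
  rel_f <- params$tail_release_frame
  if (!is.null(rel_f) && params$tail_mode == "wrapped") {
    p_rel <- params
    p_rel$tail_mode <- "released"
    released <- build_ideal_nucleosome(p_rel)$frame$xyz
  }

  a <- nuc$frame$atoms
  rm <- classify_dna_regions(nuc$topology)
  outer_bp <- rm$bp[rm$gyre != "inner_gyre"]
  heavy <- a$element != "H"
  outer_idx <- which(heavy & !is.na(a$bp) & a$bp %in% outer_bp)
  tail_idx <- which(a$role %in% c("H3-A", "H2A-A") & a$tail)

  nat <- nrow(a)
  xyz <- matrix(NA_real_, nf, 3L * nat)
  truth_rows <- list()
  tail_counts <- integer(nf)
  for (f in seq_len(nf)) {
    fr <- nuc$frame
    if (!is.null(released) && f >= rel_f) fr$xyz <- released
    for (ai in seq_along(arms)) {
      arm <- arms[ai]
      g0 <- base[base$arm == arm, ]
      g1t <- g0$gamma1 + signs[ai] * d1[f]
      g2t <- g0$gamma2 + signs[ai] * d2[f]
      fr <- rotate_arm(nuc, arm, g1t, g2t, frame = fr)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(frame = f, arm = arm, gamma1 = g1t, gamma2 = g2t)
    }
    for (arm in setdiff(c("5p", "3p"), arms)) {
      g0 <- base[base$arm == arm, ]
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(frame = f, arm = arm, gamma1 = g0$gamma1,
                   gamma2 = g0$gamma2)
    }
    tail_counts[f] <- truth_pair_count(fr$xyz[tail_idx, , drop = FALSE],
                                       fr$xyz[outer_idx, , drop = FALSE])
    if (params$noise_sd > 0)
      fr$xyz <- fr$xyz + matrix(stats::rnorm(3L * nat, 0, params$noise_sd),
                                ncol = 3L)
    xyz[f, ] <- as.vector(t(fr$xyz))
  }

  traj <- new_trajectory(a, xyz,
                         provenance = sprintf("synthetic(seed=%d)",
                                              params$seed))
  truth <- list(gamma = do.call(rbind, truth_rows),
                tail_series = data.frame(frame = seq_len(nf),
                                         count = tail_counts),
                release_frame = rel_f,
                opening_signs = signs)
  structure(list(trajectory = traj, topology = nuc$topology,
                 reference = nuc$frame, truth = truth, nucleosome = nuc),
            class = "nuc_synth_trajectory")
}

#' Write a synthetic fixture to disk
#'
#' Writes the reference structure (PDB), the trajectory (multi-model
#' PDB), the matching region configuration (YAML) and the ground truth
#' (CSV) into a directory.
#'
#' @param synth A `nuc_synth_trajectory` (or `nuc_synthetic` for a single
#'   structure).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_fixture <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(structure_pdb = file.path(dir, "structure.pdb"),
             config_yaml = file.path(dir, "config.yaml"))
  if (inherits(synth, "nuc_synth_trajectory")) {
    write_structure(synth$reference, paths[["structure_pdb"]])
    write_region_config(synth$nucleosome$config, paths[["config_yaml"]])
    paths <- c(paths, trajectory_pdb = file.path(dir, "trajectory.pdb"),
               truth_gamma_csv = file.path(dir, "truth_gamma.csv"),
               truth_tails_csv = file.path(dir, "truth_tails.csv"))
    write_trajectory(synth$trajectory, paths[["trajectory_pdb"]])
    write_table(synth$truth$gamma, paths[["truth_gamma_csv"]])
    write_table(synth$truth$tail_series, paths[["truth_tails_csv"]])
  } else {
    write_structure(synth$frame, paths[["structure_pdb"]])
    write_region_config(synth$config, paths[["config_yaml"]])
    paths <- c(paths, truth_gamma_csv = file.path(dir, "truth_gamma.csv"))
    write_table(synth$truth$gamma, paths[["truth_gamma_csv"]])
  }
  invisible(paths)
}
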