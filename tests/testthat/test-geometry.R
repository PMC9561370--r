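# Horn's closed-form quaternion solution for optimal superposition --
# an oracle independent of the SVD/Kabsch route used by the package.
horn_rmsd <- function(x, y) {
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  S <- t(xc) %*% yc
  K <- matrix(0, 4L, 4L)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

rand_rot <- function() {
  q <- rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

test_that("superposition removes rigid motion and matches the quaternion
           oracle", {
  nuc <- fix_nuc()
  fit0 <- superpose_to_reference(nuc$frame, nuc$frame, nuc$topology)
  expect_lt(fit0$rmsd, 1e-10)

  set.seed(101)
  fr <- nuc$frame
  fr$xyz <- fr$xyz %*% t(rand_rot()) +
    matrix(rep(c(30, -12, 7), each = nrow(fr$xyz)), ncol = 3L)
  fit <- superpose_to_reference(fr, nuc$frame, nuc$topology)
  expect_lt(fit$rmsd, 1e-8)

  # random 50-atom point sets: fitted RMSD equals the closed-form optimum
  # and no sampled rotation does better
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(150, sd = 8), ncol = 3L)
    y <- matrix(rnorm(150, sd = 8), ncol = 3L)
    fx <- point_frame(x); fy <- point_frame(y)
    fit <- superpose_to_reference(fy, fx, topology = NULL,
                                  selection = 1:50)
    expect_equal(fit$rmsd, horn_rmsd(x, y), tolerance = 1e-2)
    grid_best <- min(vapply(1:400, function(i) {
      yr <- sweep(y, 2L, colMeans(y)) %*% t(rand_rot())
      sqrt(mean(rowSums((sweep(x, 2L, colMeans(x)) - yr)^2)))
    }, numeric(1L)))
    expect_lte(fit$rmsd, grid_best + 1e-9)
  }
})

test_that("radius of gyration matches closed forms and a naive oracle", {
  f2 <- point_frame(matrix(c(-3, 0, 0, 3, 0, 0), ncol = 3L, byrow = TRUE))
  expect_equal(radius_of_gyration(f2, 1:2), 3)
  a <- 2.5
  cube <- as.matrix(expand.grid(c(-a, a), c(-a, a), c(-a, a)))
  expect_equal(radius_of_gyration(point_frame(cube), 1:8), a * sqrt(3))
  set.seed(11)
  x <- matrix(rnorm(1500), ncol = 3L)
  w <- runif(500, 1, 40)
  fr <- point_frame(x); fr$atoms$mass <- w
  ctr <- colSums(x * w) / sum(w)
  oracle <- sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)) / sum(w))
  expect_equal(radius_of_gyration(fr, 1:500), oracle, tolerance = 1e-10)
  fr$atoms$mass <- rep(1, 500)
  expect_equal(radius_of_gyration(fr, 1:500, mass_weighted = FALSE),
               radius_of_gyration(fr, 1:500))
  expect_error(radius_of_gyration(fr, integer(0)), "empty")
})

test_that("the dyad frame is orthonormal, axis-aligned and equivariant", {
  nuc <- fix_nuc()
  dy <- build_dyad_frame(nuc$frame, nuc$topology)
  dots <- c(sum(dy$X * dy$Y), sum(dy$X * dy$Z), sum(dy$Y * dy$Z))
  expect_lt(max(abs(dots)), 1e-8)
  expect_equal(sapply(list(dy$X, dy$Y, dy$Z), function(v) sum(v^2)),
               rep(1, 3L), tolerance = 1e-10)
  # Z within 5 degrees of the generator's superhelical axis (+z)
  expect_lt(acos(abs(dy$Z[3L])) * 180 / pi, 5)

  # rigid rotation of the reference rotates the frame identically,
  # leaving downstream angles unchanged
  set.seed(5)
  R <- rand_rot()
  fr <- nuc$frame
  fr$xyz <- fr$xyz %*% t(R)
  dy2 <- build_dyad_frame(fr, nuc$topology)
  expect_equal(dy2$X, as.vector(R %*% dy$X), tolerance = 1e-8)
  expect_equal(dy2$Z, as.vector(R %*% dy$Z), tolerance = 1e-8)
  g1 <- breathing_angles(nuc$frame, dy, nuc$topology)
  g2 <- breathing_angles(fr, dy2, nuc$topology)
  expect_equal(unlist(g1), unlist(g2), tolerance = 1e-6)
})

test_that("linker vectors point outward along the arm axis", {
  nuc <- fix_nuc()
  v3 <- linker_vector(nuc$frame, nuc$topology, "3p")
  v5 <- linker_vector(nuc$frame, nuc$topology, "5p")
  ang <- function(a, b) acos(pmin(1, sum(a * b))) * 180 / pi
  expect_lt(ang(v3, nuc$truth$arm_axes[["3p"]]), 10)
  expect_lt(ang(v5, nuc$truth$arm_axes[["5p"]]), 10)
  # endpoints method agrees on straight arms
  expect_lt(ang(linker_vector(nuc$frame, nuc$topology, "3p",
                              method = "endpoints"),
                nuc$truth$arm_axes[["3p"]]), 1)
  # file order of the atoms does not affect orientation
  fr <- nuc$frame
  ord <- rev(seq_len(nrow(fr$atoms)))
  fr$atoms <- fr$atoms[ord, ]
  fr$xyz <- fr$xyz[ord, , drop = FALSE]
  expect_lt(ang(linker_vector(fr, nuc$topology, "3p"), v3), 1e-6)
})

test_that("projection angles follow the stated sign conventions", {
  nuc <- fix_nuc()
  dy <- nuc$truth$dyad_frame
  expect_equal(unname(gamma_of_vector(dy$Z, dy)[["gamma1"]]), 0)
  # Z rotated 30 degrees toward X within the XZ plane -> gamma1 = 30
  v <- cos(pi / 6) * dy$Z + sin(pi / 6) * dy$X
  expect_equal(unname(gamma_of_vector(v, dy)[["gamma1"]]), 30,
               tolerance = 1e-10)
  expect_equal(unname(gamma_of_vector(dy$Y, dy)[["gamma2"]]), 0)
  # a vector perpendicular to the XZ plane has undefined gamma1
  expect_true(is.na(gamma_of_vector(dy$Y, dy)[["gamma1"]]))
  # configurable sign flip
  expect_equal(unname(gamma_of_vector(v, dy,
                                      flip = c(gamma1 = -1, gamma2 = 1))[["gamma1"]]),
               -30, tolerance = 1e-10)
})

test_that("min_group_distance equals the brute-force oracle", {
  f <- point_frame(matrix(c(0, 0, 0, 7, 0, 0), ncol = 3L, byrow = TRUE))
  expect_equal(min_group_distance(f, 1L, 2L), 7)
  f2 <- point_frame(matrix(c(1, 2, 3, 1, 2, 3), ncol = 3L, byrow = TRUE))
  expect_equal(min_group_distance(f2, 1L, 2L), 0)
  set.seed(21)
  x <- matrix(runif(1200, 0, 50), ncol = 3L)
  fr <- point_frame(x)
  expect_identical(min_group_distance(fr, 1:200, 201:400),
                   oracle_min_dist(x[1:200, ], x[201:400, ]))
  expect_error(min_group_distance(fr, integer(0), 1:3), "empty")
})

test_that("Rg and breathing angles are invariant under joint rigid
           transforms", {
  synth <- fix_breathing()
  fr <- get_frame(synth$trajectory, 13L)
  ref <- synth$reference
  set.seed(31)
  R <- rand_rot(); tv <- c(-20, 4, 11)
  move <- function(f) { f$xyz <- f$xyz %*% t(R) +
    matrix(rep(tv, each = nrow(f$xyz)), ncol = 3L); f }
  topo <- synth$topology
  dna <- resolve_selection(atom_selection(roles = "DNA"), ref, topo)
  g_a <- breathing_angles(superpose_to_reference(fr, ref, topo)$frame,
                          build_dyad_frame(ref, topo), topo)
  ref2 <- move(ref); fr2 <- move(fr)
  g_b <- breathing_angles(superpose_to_reference(fr2, ref2, topo)$frame,
                          build_dyad_frame(ref2, topo), topo)
  expect_equal(unlist(g_a), unlist(g_b), tolerance = 1e-6)
  expect_equal(radius_of_gyration(fr, dna), radius_of_gyration(fr2, dna),
               tolerance = 1e-6)
})
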