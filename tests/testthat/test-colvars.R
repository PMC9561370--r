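test_that("distanceInv reduces to the distance for singletons and matches
           high-precision evaluation", {
  fr <- point_frame(matrix(c(0, 0, 0, 3, 0, 0), ncol = 3L, byrow = TRUE),
                    chain = c("A", "B"))
  expect_equal(distance_inv(fr, distance_inv_spec(1L, 2L, n = 100L)), 3)
  # group2 = {(3,0,0),(4,0,0)}: d[100] = 3 * 2^(1/100)
  fr2 <- point_frame(matrix(c(0, 0, 0, 3, 0, 0, 4, 0, 0), ncol = 3L,
                            byrow = TRUE), chain = c("A", "B", "B"))
  expect_equal(distance_inv(fr2, distance_inv_spec(1L, 2:3, n = 100L)),
               3 * 2^(1 / 100), tolerance = 1e-12)
  expect_error(distance_inv_spec(1L, 2L, n = 3L), "even")
  expect_error(distance_inv_spec(1L, 2L, n = 0L), "even")
  # coincident atoms: the limit is 0, with a warning
  fr0 <- point_frame(matrix(0, 2L, 3L), chain = c("A", "B"))
  expect_warning(v <- distance_inv(fr0, distance_inv_spec(1L, 2L)),
                 "coincident")
  expect_identical(v, 0)
})

test_that("distanceInv decreases toward the true minimum as n grows,
           within its exact normalization bound", {
  set.seed(321)
  for (k in 1:100) {
    na <- sample(5:50, 1L); nb <- sample(5:50, 1L)
    x <- matrix(runif(3 * (na + nb), 0, 30), ncol = 3L)
    fr <- point_frame(x, chain = rep(c("A", "B"), c(na, nb)))
    g1 <- 1:na; g2 <- na + seq_len(nb)
    dmin <- min_group_distance(fr, g1, g2)
    vals <- vapply(c(2L, 10L, 100L), function(n)
      distance_inv(fr, distance_inv_spec(g1, g2, n = n)), numeric(1L))
    expect_true(all(diff(vals) <= 1e-9))         # non-increasing in n
    expect_true(all(vals >= dmin - 1e-9))        # bounded below by the min
    # exact upper bound: the 1/(N1*N2) normalization can inflate the
    # n-th power mean by at most (N1*N2)^(1/n)
    expect_lte(vals[3L], dmin * (na * nb)^(1 / 100) + 1e-9)
  }
})

test_that("the coordination switching function matches its closed form", {
  fr <- function(d) point_frame(matrix(c(0, 0, 0, d, 0, 0), ncol = 3L,
                                       byrow = TRUE), chain = c("A", "B"))
  spec <- coordination_spec(1L, 2L)         # d0 = 4, n = 6, m = 12
  expect_equal(coordination_number(fr(2), spec), (1 - 0.5^6) / (1 - 0.5^12),
               tolerance = 1e-12)
  expect_equal(coordination_number(fr(4), spec), 0.5)   # analytic limit
  expect_lt(coordination_number(fr(500), spec), 1e-12)  # -> 0 at infinity

  # factorization 1/(1+r^6) equals the generic ratio pointwise
  r <- c(seq(0.01, 0.999, by = 0.013), seq(1.001, 5, by = 0.013))
  generic <- (1 - r^6) / (1 - r^12)
  expect_equal(nucbreathe:::switching_value(r, 6L, 12L), generic,
               tolerance = 1e-12)
  expect_equal(nucbreathe:::switching_value(1, 6L, 12L), 0.5)

  # continuous and strictly decreasing in distance
  d <- seq(0.1, 20, by = 0.05)
  v <- vapply(d, function(dd) coordination_number(fr(dd), spec), numeric(1L))
  expect_true(all(diff(v) < 0))
  expect_lt(max(abs(diff(v))), 0.05)
  # total C bounded by N1*N2
  set.seed(13)
  x <- matrix(runif(90, 0, 5), ncol = 3L)
  frx <- point_frame(x, chain = rep(c("A", "B"), c(10L, 20L)))
  expect_lt(coordination_number(frx, coordination_spec(1:10, 11:30)),
            10 * 20)
  expect_error(coordination_spec(1L, 2L, n = 12L, m = 6L), "m > n")
})

test_that("wall energy is (k/2) delta^2 outside, zero inside, and C1 at
           the bound", {
  w <- harmonic_wall_spec(distance_inv_spec(1L, 2L), lower = 12, k = 10)
  expect_identical(wall_energy(14, w), 0)
  expect_equal(wall_energy(10, w), 20)            # (10/2) * 2^2
  wu <- harmonic_wall_spec(coordination_spec(1L, 2L), upper = 0, k = 10)
  expect_identical(wall_energy(0, wu), 0)
  expect_equal(wall_energy(0.3, wu), 0.5 * 10 * 0.09)
  # C1 continuity: numerical derivative approaches 0 at the bound
  eps <- 1e-6
  expect_lt((wall_energy(12 - eps, w) - wall_energy(12, w)) / eps, 1e-4)
  expect_error(harmonic_wall_spec(distance_inv_spec(1L, 2L)), "lower")
})

test_that("steered centers ramp linearly and clamp at the end", {
  s <- steered_spec(distance_inv_spec(1L, 2L), from = 5, to = 15,
                    duration = 250, k = 10)
  expect_identical(steered_center(0, s), 5)
  expect_identical(steered_center(125, s), 10)
  expect_identical(steered_center(250, s), 15)
  expect_identical(steered_center(400, s), 15)    # clamped
  s2 <- steered_spec(distance_inv_spec(1L, 2L), from = 32, to = 12,
                     duration = 250)
  expect_identical(steered_center(250, s2), 12)
  expect_error(steered_center(-1, s), "negative")
})

test_that("protocol evaluation flags wall violations and fills one row per
           frame and term", {
  nuc <- fix_nuc()   # wrapped tails: tail_release walls must be violated
  tr <- one_frame_traj(nuc$frame)
  prot <- bias_protocol_preset("tail_release")
  ev <- evaluate_protocol(tr, prot, nuc$topology)
  expect_identical(nrow(ev), n_frames(tr) * length(prot$terms))
  expect_true(all(ev$energy_kcal_mol[ev$term == "wall_dmin_tails_outer"] > 0))
  expect_true(all(ev$active))

  rel <- build_ideal_nucleosome(synthetic_params(seed = 42L,
                                                 tail_mode = "released"))
  ev2 <- evaluate_protocol(one_frame_traj(rel$frame), prot, rel$topology)
  expect_true(all(ev2$energy_kcal_mol < 1e-3))   # constraints satisfied
  expect_false(any(ev2$active))
})

test_that("preset protocols serialize exactly the published numbers", {
  txt <- export_bias_config(bias_protocol_preset("pou_hd_insertion"))
  for (needle in c("centers 5", "targetCenters 15", "centers 32",
                   "targetCenters 12", "centers 58", "targetCenters 28",
                   "targetTime 250", "forceConstant 10", "lowerWalls 30",
                   "lowerWalls 20", "upperWalls 0", "exponent 100",
                   "cutoff 4", "expNumer 6", "expDenom 12"))
    expect_true(grepl(needle, txt, fixed = TRUE), label = needle)
  txt2 <- export_bias_config(bias_protocol_preset("tail_release"))
  expect_true(grepl("lowerWalls 12", txt2, fixed = TRUE))
  expect_true(grepl("upperWalls 0", txt2, fixed = TRUE))
})

test_that("exported configurations match the golden files byte for byte", {
  for (preset in c("tail_release", "pou_hd_insertion")) {
    txt <- export_bias_config(bias_protocol_preset(preset))
    golden <- readChar(test_path(paste0("golden_", preset, ".colvars")),
                       1e6)
    expect_identical(txt, golden)
  }
})

test_that("export -> parse -> export is a fixpoint, and the empty protocol
           exports a bare header", {
  for (preset in c("tail_release", "pou_hd_insertion")) {
    txt <- export_bias_config(bias_protocol_preset(preset))
    expect_identical(export_bias_config(parse_bias_config(txt)), txt)
  }
  empty <- bias_protocol(name = "empty")
  txt <- export_bias_config(empty)
  expect_identical(txt, "# colvars bias protocol: empty\n")
  expect_identical(length(parse_bias_config(txt)$terms), 0L)
})
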