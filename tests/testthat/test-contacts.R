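test_that("the 4.5 A cutoff is strict", {
  mk <- function(d) point_frame(matrix(c(0, 0, 0, d, 0, 0), ncol = 3L,
                                       byrow = TRUE),
                                chain = c("A", "B"))
  spec <- contact_spec(1L, 2L)
  expect_identical(count_contacts(mk(4.4), spec), 1L)
  expect_identical(count_contacts(mk(4.6), spec), 0L)
  expect_identical(count_contacts(mk(4.5), spec), 0L)  # strictly closer than
})

test_that("contact counts equal the brute-force oracle on 100 seeded
           configurations at both granularities", {
  set.seed(2024)
  for (k in 1:100) {
    na <- sample(10:60, 1L); nb <- sample(10:60, 1L)
    side <- runif(1, 15, 40)
    xa <- matrix(runif(3 * na, 0, side), ncol = 3L)
    xb <- matrix(runif(3 * nb, 0, side), ncol = 3L)
    fr <- point_frame(rbind(xa, xb),
                      chain = rep(c("A", "B"), c(na, nb)),
                      resno = c(rep(1:5, length.out = na),
                                rep(1:7, length.out = nb)))
    cutoff <- runif(1, 2, 8)
    spec <- contact_spec(1:na, na + seq_len(nb), cutoff = cutoff)
    expect_identical(as.integer(count_contacts(fr, spec)),
                     oracle_pair_count(xa, xb, cutoff))
    # residue-level: oracle recount over residue pairs
    spec_r <- contact_spec(1:na, na + seq_len(nb), cutoff = cutoff,
                           granularity = "residue-bp")
    keys <- 0L
    for (ra in 1:5) for (rb in 1:7) {
      ia <- which(rep(1:5, length.out = na) == ra)
      ib <- which(rep(1:7, length.out = nb) == rb)
      if (length(ia) && length(ib) &&
          oracle_pair_count(xa[ia, , drop = FALSE],
                            xb[ib, , drop = FALSE], cutoff) > 0L)
        keys <- keys + 1L
    }
    expect_identical(as.integer(count_contacts(fr, spec_r)), keys)
    # symmetry and granularity ordering
    spec_sw <- contact_spec(na + seq_len(nb), 1:na, cutoff = cutoff)
    expect_identical(count_contacts(fr, spec_sw), count_contacts(fr, spec))
    expect_gte(count_contacts(fr, spec), count_contacts(fr, spec_r))
  }
})

test_that("raising the cutoff never decreases a count", {
  set.seed(9)
  x <- matrix(runif(300, 0, 20), ncol = 3L)
  fr <- point_frame(x, chain = rep(c("A", "B"), each = 50L))
  counts <- vapply(seq(1, 12, by = 0.5), function(co)
    count_contacts(fr, contact_spec(1:50, 51:100, cutoff = co)),
    integer(1L))
  expect_true(all(diff(counts) >= 0L))
})

test_that("per-gyre counts add up to the all-DNA count (partition
           additivity)", {
  nuc <- fix_nuc()
  tails <- atom_selection(roles = "H3-A", segment = "tail")
  total <- count_contacts(nuc$frame,
                          contact_spec(tails, atom_selection(roles = "DNA")),
                          nuc$topology)
  parts <- vapply(c("inner_gyre", "outer_gyre_5p", "outer_gyre_3p"),
                  function(r) count_contacts(
                    nuc$frame,
                    contact_spec(tails, atom_selection(roles = "DNA",
                                                       dna_region = r)),
                    nuc$topology), integer(1L))
  expect_identical(sum(parts), total)
})

test_that("contact series are constant on frozen input and symmetric in
           group order", {
  nuc <- fix_nuc()
  xyz <- matrix(rep(as.vector(t(nuc$frame$xyz)), 4L), nrow = 4L,
                byrow = TRUE)
  frozen <- nucbreathe:::new_trajectory(nuc$frame$atoms, xyz, "frozen")
  sA <- atom_selection(roles = "H3-A", segment = "tail")
  sB <- atom_selection(roles = "DNA", dna_region = "outer_gyres")
  cs <- contact_series(frozen, contact_spec(sA, sB), nuc$topology)
  expect_identical(length(unique(cs$count)), 1L)
  cs_swap <- contact_series(frozen, contact_spec(sB, sA), nuc$topology)
  expect_identical(cs$count, cs_swap$count)
})

test_that("stable-contact flags are strict at the 75% threshold", {
  # one residue-bp pair in contact for exactly 750, then 751, of 1000 frames
  atoms <- point_frame(matrix(0, 2L, 3L), chain = c("A", "I"))$atoms
  atoms$bp[2L] <- 5L
  near <- c(0, 0, 0, 3, 0, 0)
  far <- c(0, 0, 0, 50, 0, 0)
  for (n_in in c(750L, 751L)) {
    xyz <- rbind(matrix(rep(near, n_in), ncol = 6L, byrow = TRUE),
                 matrix(rep(far, 1000L - n_in), ncol = 6L, byrow = TRUE))
    tr <- nucbreathe:::new_trajectory(atoms, xyz, "edge")
    prof <- stable_contact_profile(tr, 1L, 2L)
    expect_equal(prof$profile$occupancy, n_in / 1000)
    expect_identical(prof$profile$stable, n_in > 750L)
  }
})

test_that("stable-contact occupancies equal a brute-force recount", {
  set.seed(77)
  n_res <- 4L; n_bp <- 6L; nf <- 30L
  chain <- c(rep("A", n_res), rep("I", n_bp))
  fr0 <- point_frame(matrix(0, n_res + n_bp, 3L), chain = chain,
                     resno = c(1:n_res, 1:n_bp))
  fr0$atoms$bp[fr0$atoms$chain == "I"] <- 1:n_bp
  xyz <- matrix(runif(nf * 3L * (n_res + n_bp), 0, 12), nrow = nf)
  tr <- nucbreathe:::new_trajectory(fr0$atoms, xyz, "rand")
  prof <- stable_contact_profile(tr, 1:n_res, n_res + 1:n_bp,
                                 threshold = 0.4)
  for (r in 1:n_res) for (b in 1:n_bp) {
    hits <- 0L
    for (f in 1:nf) {
      xa <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      if (oracle_pair_count(xa[r, , drop = FALSE],
                            xa[n_res + b, , drop = FALSE], 4.5) > 0L)
        hits <- hits + 1L
    }
    row <- prof$profile[prof$profile$resno == r & prof$profile$bp == b, ]
    expect_equal(row$occupancy, hits / nf)
    expect_identical(row$stable, hits / nf > 0.4)
  }
  # marginals recount
  agg <- stats::aggregate(stable ~ bp, prof$profile, sum)
  expect_identical(prof$per_bp$n_stable_residues, agg$stable)
})

test_that("the subdomain-gyre table reproduces generator truth and is
           degenerate on frozen input", {
  nuc <- build_ideal_nucleosome(synthetic_params(seed = 4L,
                                                 tf_mode = "bridging"))
  tab <- subdomain_gyre_contact_table(one_frame_traj(nuc$frame),
                                      nuc$topology)
  merged <- merge(tab, nuc$truth$tf_contacts,
                  by = c("subdomain", "dna_part", "gyre"))
  expect_identical(nrow(merged), 12L)
  expect_equal(merged$median, merged$count)
  expect_equal(merged$p5, merged$median)   # single frame: p5 = med = p95
  expect_equal(merged$p95, merged$median)
  # backbone-only placement leaves the bases columns at zero
  nuc2 <- build_ideal_nucleosome(synthetic_params(
    seed = 4L, tf_mode = "free", tf_attach = "backbone",
    tf_site = c(140L, 148L)))
  tab2 <- subdomain_gyre_contact_table(one_frame_traj(nuc2$frame),
                                       nuc2$topology)
  expect_true(all(tab2$median[tab2$subdomain == "POU_S" &
                                tab2$dna_part == "base"] == 0))
  expect_gt(sum(tab2$median[tab2$subdomain == "POU_S" &
                              tab2$dna_part == "backbone"]), 0)
})
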