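# Shared fixtures, built once per test run.

# a bare frame around raw coordinates, for oracle-style tests
point_frame <- function(xyz, chain = rep("A", nrow(xyz)),
                        resno = seq_len(nrow(xyz)),
                        elety = "CA", element = "C", mass = 12.011,
                        bp = NA_integer_) {
  a <- data.frame(eleno = seq_len(nrow(xyz)), elety = elety, resid = "ALA",
                  chain = chain, resno = resno, element = element,
                  mass = mass, role = chain, bp = bp, tail = FALSE,
                  subdomain = NA_character_, dna_part = NA_character_,
                  stringsAsFactors = FALSE)
  nucbreathe:::new_frame(a, xyz)
}

one_frame_traj <- function(frame) {
  nucbreathe:::new_trajectory(frame$atoms,
                              matrix(as.vector(t(frame$xyz)), nrow = 1L),
                              "test")
}

default_config <- function(n_bp = 168L, tf = FALSE, ...) {
  chains <- list(I = "DNA-I", J = "DNA-J", A = "H3-A", B = "H4-A",
                 C = "H2A-A", D = "H2B-A", E = "H3-B", F = "H4-B",
                 G = "H2A-B", H = "H2B-B")
  if (tf) chains$T <- "TF"
  utils::modifyList(list(n_bp = n_bp, species = "human", chains = chains),
                    list(...))
}

# expensive shared fixtures, memoized in the test environment
.fix <- new.env()

fix_nuc <- function() {
  if (is.null(.fix$nuc))
    .fix$nuc <- build_ideal_nucleosome(synthetic_params(seed = 42L))
  .fix$nuc
}

fix_breathing <- function() {
  if (is.null(.fix$breathing))
    .fix$breathing <- generate_breathing_trajectory(synthetic_params(
      seed = 42L, frames = 25L,
      opening = list(arm = "3p", dgamma1 = c(0, 40), dgamma2 = c(0, 0))))
  .fix$breathing
}

# naive O(N^2) double-loop contact count (the brute-force oracle)
oracle_pair_count <- function(xa, xb, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      d2 <- (xa[i, 1] - xb[j, 1])^2 + (xa[i, 2] - xb[j, 2])^2 +
        (xa[i, 3] - xb[j, 3])^2
      if (d2 < cutoff^2) n <- n + 1L
    }
  }
  n
}

oracle_min_dist <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      d2 <- (xa[i, 1] - xb[j, 1])^2 + (xa[i, 2] - xb[j, 2])^2 +
        (xa[i, 3] - xb[j, 3])^2
      if (d2 < best) best <- d2
    }
  }
  sqrt(best)
}
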