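## Topology: chain/residue role maps, DNA region partitions, histone tails.

#' Histone tail residue presets
#'
#' Literal N-terminal (and H2A C-terminal) tail definitions for human and
#' Drosophila histones, as residue ranges on each histone chain.
#'
#' @param species `"human"` or `"drosophila"`.
#' @return Named list mapping histone type (H3, H4, H2A, H2B) to an integer
#'   vector of tail residue numbers.
#' @export
tail_preset <- function(species = c("human", "drosophila")) {
  species <- match.arg(species)
  if (species == "human") {
    list(H3  = 1:45,
         H4  = 1:32,
         H2A = c(1:18, 119:129),
         H2B = 1:33)
  } else {
    list(H3  = 1:45,
         H4  = 1:32,
         H2A = c(1:17, 116:124),
         H2B = 1:31)
  }
}

.known_role_types <- c("DNA", "H3", "H4", "H2A", "H2B", "TF")

## role strings look like "DNA-I", "DNA-J", "H3-A", "H2A-B", "TF"
role_type <- function(role) sub("-[A-Za-z0-9]+$", "", role)

#' Build a nucleosome topology from a region configuration
#'
#' The configuration maps chain identifiers to nucleosome roles (two DNA
#' strands, histone copies, optionally a transcription factor), selects a
#' histone-tail species preset and declares TF subdomain residue ranges.
#' It can be given as a parsed list or as the path to a YAML document with
#' keys `n_bp`, `chains`, `species`, and optionally `strand_lengths`,
#' `regions`, `tf_subdomains` and (for `species: custom`) `tails`.
#'
#' @param config A list or path to a YAML file.
#' @return An object of class `nuc_topology`.
#' @examples
#' cfg <- list(
#'   n_bp = 168, species = "human",
#'   chains = list(I = "DNA-I", J = "DNA-J", A = "H3-A", B = "H4-A",
#'                 C = "H2A-A", D = "H2B-A", E = "H3-B", F = "H4-B",
#'                 G = "H2A-B", H = "H2B-B"))
#' topo <- build_topology(cfg)
#' topo$n_bp
#' @export
build_topology <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")

  n_bp <- config$n_bp
  if (is.null(n_bp)) stop("config must declare 'n_bp'")
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 1L) stop("'n_bp' must be a positive integer")

  chains <- unlist(config$chains)
  if (is.null(chains) || is.null(names(chains)))
    stop("config must declare a named 'chains' map (chain id -> role)")
  if (anyDuplicated(names(chains)))
    stop("duplicate chain id in 'chains'")
  if (anyDuplicated(chains))
    stop("duplicate role in 'chains': every chain must have exactly one role ",
         "and every role exactly one chain")
  bad <- chains[!role_type(chains) %in% .known_role_types]
  if (length(bad))
    stop("unknown chain role(s): ", paste(bad, collapse = ", "))

  dna_roles <- chains[role_type(chains) == "DNA"]
  if (length(dna_roles) != 2L)
    stop("config must name exactly two DNA chains (roles DNA-I and DNA-J)")
  if (!all(sort(unname(dna_roles)) == c("DNA-I", "DNA-J")))
    stop("DNA chain roles must be DNA-I (reference strand) and DNA-J")

  strand_lengths <- config$strand_lengths %||% c(n_bp, n_bp)
  strand_lengths <- as.integer(unlist(strand_lengths))
  if (length(strand_lengths) != 2L)
    stop("'strand_lengths' must have two entries")
  if (strand_lengths[1L] != strand_lengths[2L])
    stop(sprintf("DNA strands must have equal residue counts (got %d and %d)",
                 strand_lengths[1L], strand_lengths[2L]))
  if (strand_lengths[1L] != n_bp)
    stop(sprintf("strand length (%d) must equal n_bp (%d)",
                 strand_lengths[1L], n_bp))

  species <- config$species %||% "human"
  if (!species %in% c("human", "drosophila", "custom"))
    stop("'species' must be one of human, drosophila, custom")

  if (species == "custom") {
    tails <- config$tails
    if (is.null(tails)) stop("species 'custom' requires an explicit 'tails' map")
    tails <- lapply(tails, function(rr) {
      if (is.list(rr)) {
        ## list of [lo, hi] ranges
        sort(unique(unlist(lapply(rr, function(r) seq.int(r[[1L]], r[[2L]])))))
      } else {
        as.integer(rr)
      }
    })
  } else {
    tails <- tail_preset(species)
  }

  regions <- config$regions %||% list()
  region_sizes <- list(core  = as.integer(regions$core %||% 146L),
                       outer = as.integer(regions$outer_gyre %||% 40L))

  tf <- NULL
  if (any(role_type(chains) == "TF")) {
    tfs <- config$tf_subdomains %||%
      list(POU_S = c(1L, 75L), linker = c(76L, 89L), POU_HD = c(90L, 145L))
    tf <- lapply(tfs, function(r) as.integer(c(r[[1L]], r[[2L]])))
    if (!all(c("POU_S", "POU_HD") %in% names(tf)))
      stop("'tf_subdomains' must define at least POU_S and POU_HD")
  }

  topo <- structure(
    list(n_bp = n_bp,
         chain_map = chains,
         species = species,
         tails = tails,
         region_sizes = region_sizes,
         tf_subdomains = tf),
    class = "nuc_topology")
  topo
}

#' @export
print.nuc_topology <- function(x, ...) {
  cat(sprintf("<nuc_topology> %d bp, species=%s, %d chains%s\n",
              x$n_bp, x$species, length(x$chain_map),
              if (is.null(x$tf_subdomains)) "" else ", TF bound"))
  invisible(x)
}

role_for_chain <- function(topology, chain) {
  r <- topology$chain_map[match(chain, names(topology$chain_map))]
  unname(r)
}

chain_for_role <- function(topology, role) {
  i <- match(role, topology$chain_map)
  if (is.na(i)) stop("no chain with role '", role, "' in topology")
  names(topology$chain_map)[i]
}

#' Classify DNA base pairs into core/linker and gyre regions
#'
#' Produces the two independent base-pair partitions used throughout:
#' core vs 5'/3' linker DNA (defaults 146/11/11 for a 168-bp construct,
#' core centered on the dyad), and inner gyre vs 5'/3' outer gyres
#' (defaults 88/40/40; the outer gyres are the terminal stretches at each
#' DNA end). Base pairs are indexed 1..n_bp along the reference strand
#' 5'->3'.
#'
#' When `n_bp - core` is odd the extra base pair is assigned to the 3'
#' linker; likewise any odd remainder of the gyre partition enlarges the
#' inner gyre symmetrically from the 5' side.
#'
#' @param topology A `nuc_topology`.
#' @param core Core size in bp (default from the topology, 146).
#' @param outer Outer-gyre size in bp at each end (default 40).
#' @return An object of class `nuc_region_map`: a data frame with columns
#'   `bp`, `region` (core/linker_5p/linker_3p) and `gyre`
#'   (inner_gyre/outer_gyre_5p/outer_gyre_3p).
#' @export
classify_dna_regions <- function(topology,
                                 core = topology$region_sizes$core,
                                 outer = topology$region_sizes$outer) {
  n <- topology$n_bp
  core <- as.integer(core); outer <- as.integer(outer)
  if (core > n) stop(sprintf("core size (%d) exceeds n_bp (%d)", core, n))
  if (2L * outer > n)
    stop(sprintf("outer gyres (2 x %d bp) exceed n_bp (%d)", outer, n))

  rem <- n - core
  l5 <- rem %/% 2L
  l3 <- rem - l5                       # odd leftover goes 3'
  region <- c(rep("linker_5p", l5), rep("core", core), rep("linker_3p", l3))

  gyre <- c(rep("outer_gyre_5p", outer),
            rep("inner_gyre", n - 2L * outer),
            rep("outer_gyre_3p", outer))

  out <- data.frame(bp = seq_len(n),
                    region = factor(region, levels = c("linker_5p", "core",
                                                       "linker_3p")),
                    gyre = factor(gyre, levels = c("outer_gyre_5p",
                                                   "inner_gyre",
                                                   "outer_gyre_3p")))
  class(out) <- c("nuc_region_map", class(out))
  out
}

#' Tail residue sets for every histone copy in a topology
#'
#' @param topology A `nuc_topology`.
#' @return Named list: for each histone role present (e.g. `H3-A`), the
#'   integer vector of tail residue numbers from the species preset (or the
#'   custom map). An empty vector means a tail-less ("TL") histone.
#' @export
tail_residues <- function(topology) {
  roles <- topology$chain_map[role_type(topology$chain_map) %in%
                                c("H3", "H4", "H2A", "H2B")]
  out <- lapply(unname(roles), function(r) {
    tl <- topology$tails[[role_type(r)]]
    if (is.null(tl)) integer(0) else as.integer(tl)
  })
  names(out) <- unname(roles)
  out
}

## Standard nucleic-acid heavy-atom nomenclature. Sugar atoms (including
## C1') count as backbone together with the phosphate; the glycosidic
## nitrogen and everything beyond belongs to the base.
.backbone_atoms <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
                     "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
                     "O2'", "C1'",
                     "O5*", "C5*", "C4*", "O4*", "C3*", "O3*", "C2*",
                     "O2*", "C1*")
.base_atoms <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "N6",
                 "N7", "C8", "N9", "O6", "N2", "O4", "C7", "C5M")

#' Partition DNA atom names into base vs backbone
#'
#' Phosphate and sugar atoms (including C1') are classified as backbone;
#' nucleobase atoms as base. Hydrogens are not part of either set (contact
#' and CV groups exclude them regardless).
#'
#' @param atom_name Character vector of atom names.
#' @param strict If `TRUE` (default) an unrecognized heavy-atom name is an
#'   error; otherwise it falls back to `"backbone"` with a warning.
#' @return Character vector of `"base"`/`"backbone"` (NA for hydrogens).
#' @examples
#' partition_dna_atoms(c("P", "N1", "C1'"))
#' @export
partition_dna_atoms <- function(atom_name, strict = TRUE) {
  out <- rep(NA_character_, length(atom_name))
  is_h <- grepl("^[0-9]*H", atom_name)
  out[atom_name %in% .backbone_atoms] <- "backbone"
  out[atom_name %in% .base_atoms] <- "base"
  unknown <- is.na(out) & !is_h
  if (any(unknown)) {
    if (strict) {
      stop("unrecognized DNA atom name(s): ",
           paste(unique(atom_name[unknown]), collapse = ", "))
    }
    warning("unrecognized DNA atom name(s) classified as backbone: ",
            paste(unique(atom_name[unknown]), collapse = ", "))
    out[unknown] <- "backbone"
  }
  out
}

#' Write a region configuration to YAML
#'
#' @param config Configuration list (as accepted by [build_topology()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
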