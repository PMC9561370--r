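## Structure/trajectory I/O and binding of atoms to topology roles.

.solvent_resid <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SPC", "SOL",
                    "NA", "CL", "K", "MG", "ZN", "CA2", "SOD", "CLA",
                    "POT", "CAL", "NA+", "CL-", "K+", "MG2")

## Standard atomic masses (amu), used when inferring mass from the element.
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.973762, S = 32.06, FE = 55.845, MG = 24.305,
                   `NA` = 22.98977, K = 39.0983, CL = 35.45, ZN = 65.38)

infer_element <- function(elety, elesy = NULL) {
  ele <- rep(NA_character_, length(elety))
  if (!is.null(elesy)) {
    es <- toupper(trimws(elesy))
    ok <- !is.na(es) & nzchar(es)
    ele[ok] <- es[ok]
  }
  miss <- is.na(ele)
  if (any(miss))
    ele[miss] <- toupper(suppressWarnings(bio3d::atom2ele(elety[miss])))
  ele
}

element_mass <- function(element) {
  m <- .element_mass[match(element, names(.element_mass))]
  if (anyNA(m)) {
    ## fall back to bio3d's periodic table for anything exotic
    miss <- is.na(m)
    m[miss] <- suppressWarnings(bio3d::atom2mass(element[miss], rescue = TRUE))
  }
  unname(m)
}

#' Bind an atom table to topology roles
#'
#' Assigns each atom its topology role, base-pair index (DNA), tail flag
#' (histones), TF subdomain, and base/backbone classification (DNA).
#' Solvent and ion residues are dropped; atoms on chains absent from the
#' topology are flagged `"unassigned"`.
#'
#' @param atoms Atom data frame with columns `elety`, `resid`, `chain`,
#'   `resno`, `element`, `mass`.
#' @param topology A `nuc_topology`.
#' @param strict_dna Passed to [partition_dna_atoms()].
#' @return The atom table with `role`, `bp`, `tail`, `subdomain`,
#'   `dna_part` columns added (solvent rows removed).
#' @keywords internal
bind_topology <- function(atoms, topology, strict_dna = TRUE) {
  keep <- !(toupper(atoms$resid) %in% .solvent_resid)
  atoms <- atoms[keep, , drop = FALSE]

  missing_chain <- setdiff(names(topology$chain_map), unique(atoms$chain))
  if (length(missing_chain))
    stop("chain(s) declared in topology but absent from structure: ",
         paste(missing_chain, collapse = ", "))

  role <- role_for_chain(topology, atoms$chain)
  role[is.na(role)] <- "unassigned"
  atoms$role <- role

  n <- topology$n_bp
  atoms$bp <- NA_integer_
  i1 <- role == "DNA-I"; i2 <- role == "DNA-J"
  atoms$bp[i1] <- atoms$resno[i1]
  atoms$bp[i2] <- n + 1L - atoms$resno[i2]
  if (any(!is.na(atoms$bp) & (atoms$bp < 1L | atoms$bp > n)))
    stop("DNA residue numbers outside 1..n_bp")

  atoms$dna_part <- NA_character_
  isdna <- i1 | i2
  if (any(isdna))
    atoms$dna_part[isdna] <- partition_dna_atoms(atoms$elety[isdna],
                                                 strict = strict_dna)

  atoms$tail <- FALSE
  tails <- tail_residues(topology)
  for (r in names(tails)) {
    sel <- atoms$role == r & atoms$resno %in% tails[[r]]
    atoms$tail[sel] <- TRUE
  }

  atoms$subdomain <- NA_character_
  if (!is.null(topology$tf_subdomains)) {
    tf <- role_type(atoms$role) == "TF"
    for (sd in names(topology$tf_subdomains)) {
      r <- topology$tf_subdomains[[sd]]
      atoms$subdomain[tf & atoms$resno >= r[1L] & atoms$resno <= r[2L]] <- sd
    }
  }

  if (!nrow(atoms)) stop("zero atoms after role binding")
  atoms
}

new_frame <- function(atoms, xyz, frame = 1L, time_ns = NA_real_) {
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3L)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be strictly positive")
  structure(list(atoms = atoms, xyz = xyz, frame = as.integer(frame),
                 time_ns = time_ns),
            class = "nuc_frame")
}

#' @export
print.nuc_frame <- function(x, ...) {
  cat(sprintf("<nuc_frame> %d atoms, %d chains, frame %d\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), x$frame))
  invisible(x)
}

pdb_to_atoms <- function(pdb, strict_dna = TRUE) {
  at <- pdb$atom
  element <- infer_element(at$elety,
                           if ("elesy" %in% names(at)) at$elesy else NULL)
  data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
              chain = at$chain, resno = at$resno,
              element = element, mass = element_mass(element),
              stringsAsFactors = FALSE)
}

#' Read a structure file and bind it to a topology
#'
#' @param path PDB (or PDBx/mmCIF, by extension `.cif`) file.
#' @param topology A `nuc_topology`; all its chains must be present.
#' @param strict_dna If `TRUE`, unrecognized DNA atom names are an error.
#' @return A `nuc_frame`. Hydrogens are retained but are excluded from all
#'   contact and collective-variable groups; solvent and ions are dropped.
#' @export
read_structure <- function(path, topology, strict_dna = TRUE) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  atoms <- pdb_to_atoms(pdb)
  keep <- !(toupper(atoms$resid) %in% .solvent_resid)
  xyz <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)[keep, , drop = FALSE]
  atoms <- bind_topology(atoms, topology, strict_dna = strict_dna)
  new_frame(atoms, xyz)
}

#' Write a frame as PDB
#'
#' @param frame A `nuc_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  a <- frame$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(frame$xyz)),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, elesy = a$element)
  invisible(path)
}

new_trajectory <- function(atoms, xyz, provenance = "memory",
                           time_ns = NULL) {
  stopifnot(ncol(xyz) == 3L * nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz),
                 time_ns = time_ns, provenance = provenance),
            class = "nuc_trajectory")
}

#' @export
print.nuc_trajectory <- function(x, ...) {
  cat(sprintf("<nuc_trajectory> %d frames x %d atoms (%s)\n",
              x$n_frames, nrow(x$atoms), x$provenance))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `nuc_trajectory`.
#' @export
n_frames <- function(trajectory) trajectory$n_frames

#' Extract one frame from a trajectory
#'
#' @param trajectory A `nuc_trajectory`.
#' @param i Frame index (1-based).
#' @return A `nuc_frame`.
#' @export
get_frame <- function(trajectory, i) {
  if (i < 1L || i > trajectory$n_frames) stop("frame index out of range")
  xyz <- matrix(trajectory$xyz[i, ], ncol = 3L, byrow = TRUE)
  t_ns <- if (is.null(trajectory$time_ns)) NA_real_ else trajectory$time_ns[i]
  new_frame(trajectory$atoms, xyz, frame = i, time_ns = t_ns)
}

#' Read a trajectory (multi-model PDB or DCD, possibly segmented)
#'
#' Multiple paths are concatenated into one seamless handle (e.g. a run and
#' its continuation). DCD files carry no atom table, so `topology` binding
#' uses the accompanying `structure` frame; a multi-model PDB is
#' self-describing.
#'
#' @param paths Character vector of trajectory files (`.pdb` or `.dcd`).
#' @param topology A `nuc_topology`.
#' @param structure Optional `nuc_frame` providing the atom table (required
#'   for DCD input).
#' @param stride Keep every `stride`-th frame.
#' @param begin,end Frame-range selection (1-based, applied after
#'   concatenation, before stride).
#' @param strict_dna Passed to [partition_dna_atoms()].
#' @return A `nuc_trajectory`.
#' @export
read_trajectory <- function(paths, topology, structure = NULL, stride = 1L,
                            begin = 1L, end = NULL, strict_dna = TRUE) {
  atoms <- NULL
  xyz_parts <- list()
  for (p in paths) {
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      if (is.null(structure))
        stop("DCD input requires a 'structure' frame for the atom table")
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
      a <- structure$atoms
      if (ncol(xyz) != 3L * nrow(a))
        stop(sprintf("atom-count mismatch: DCD has %d atoms, structure %d",
                     ncol(xyz) %/% 3L, nrow(a)))
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
      a <- pdb_to_atoms(pdb)
      keep <- !(toupper(a$resid) %in% .solvent_resid)
      a <- bind_topology(a, topology, strict_dna = strict_dna)
      xyz <- pdb$xyz
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
      if (any(!keep)) {
        ki <- as.vector(t(outer(which(keep), 1:3,
                                function(i, k) 3L * (i - 1L) + k)))
        xyz <- xyz[, ki, drop = FALSE]
      }
    }
    if (is.null(atoms)) {
      atoms <- a
    } else if (nrow(a) != nrow(atoms) ||
               !identical(a$elety, atoms$elety) ||
               !identical(a$chain, atoms$chain)) {
      stop("trajectory segments have mismatching atom tables")
    }
    xyz_parts[[length(xyz_parts) + 1L]] <- xyz
  }
  xyz <- do.call(rbind, xyz_parts)
  if (is.null(end)) end <- nrow(xyz)
  if (begin < 1L || end > nrow(xyz) || begin > end)
    stop("invalid frame range")
  idx <- seq.int(begin, end, by = stride)
  new_trajectory(atoms, xyz[idx, , drop = FALSE],
                 provenance = paste(paths, collapse = "+"))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory A `nuc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  a <- trajectory$atoms
  bio3d::write.pdb(file = path, xyz = trajectory$xyz,
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Write records as a tidy delimited file
#'
#' Deterministic column order, fixed floating precision, header row kept as
#' given (column names carry units, e.g. `Rg_A`, `gamma1_5p_deg`).
#'
#' @param records A data frame.
#' @param path Output path (`.csv` or `.tsv` by extension).
#' @param digits Decimal places for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 4L) {
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf(paste0("%.", digits, "f"),
                                                 out[[j]])
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
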