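## Declarative atom selections resolved against a bound frame.

#' Describe an atom selection
#'
#' A lightweight declarative selection resolved against a topology-bound
#' frame by [resolve_selection()]. All criteria are combined with AND;
#' hydrogens are excluded unless `heavy = FALSE`.
#'
#' @param roles Character vector of roles (`"DNA-I"`, `"H3-A"`, `"TF"`, ...)
#'   or role types (`"DNA"`, `"H3"` matches both copies).
#' @param dna_region One of `"core"`, `"linker_5p"`, `"linker_3p"`,
#'   `"inner_gyre"`, `"outer_gyre_5p"`, `"outer_gyre_3p"`,
#'   `"outer_gyres"`, or `NULL`.
#' @param dna_part `"all"`, `"base"` or `"backbone"`.
#' @param segment For histones: `"all"`, `"tail"` or `"globular"`.
#' @param subdomain TF subdomain name (`"POU_S"`, `"POU_HD"`, `"linker"`).
#' @param bp Integer vector restricting DNA base-pair indices.
#' @param elety Restrict to these atom names (e.g. `"CA"`, `"P"`).
#' @param heavy Exclude hydrogens (default `TRUE`).
#' @return An object of class `nuc_selection`.
#' @export
atom_selection <- function(roles = NULL, dna_region = NULL,
                           dna_part = c("all", "base", "backbone"),
                           segment = c("all", "tail", "globular"),
                           subdomain = NULL, bp = NULL, elety = NULL,
                           heavy = TRUE) {
  structure(list(roles = roles, dna_region = dna_region,
                 dna_part = match.arg(dna_part),
                 segment = match.arg(segment),
                 subdomain = subdomain, bp = bp, elety = elety,
                 heavy = heavy),
            class = "nuc_selection")
}

#' Resolve a selection to atom row indices
#'
#' @param sel A `nuc_selection`, or directly an integer vector of atom row
#'   indices (returned unchanged).
#' @param frame A `nuc_frame` whose atoms were bound to `topology`.
#' @param topology The `nuc_topology` (needed for region classification).
#' @return Integer vector of atom row indices into `frame$atoms`.
#' @export
resolve_selection <- function(sel, frame, topology) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "nuc_selection"))
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (isTRUE(sel$heavy)) keep <- keep & a$element != "H"
  if (!is.null(sel$roles)) {
    keep <- keep & (a$role %in% sel$roles | role_type(a$role) %in% sel$roles)
  }
  if (!is.null(sel$dna_region)) {
    rm <- classify_dna_regions(topology)
    want <- sel$dna_region
    if (identical(want, "outer_gyres"))
      want <- c("outer_gyre_5p", "outer_gyre_3p")
    bp_ok <- rep(FALSE, topology$n_bp)
    for (w in want) {
      if (w %in% levels(rm$region)) {
        bp_ok[rm$bp[rm$region == w]] <- TRUE
      } else if (w %in% levels(rm$gyre)) {
        bp_ok[rm$bp[rm$gyre == w]] <- TRUE
      } else stop("unknown dna_region: ", w)
    }
    keep <- keep & !is.na(a$bp) & bp_ok[pmax(a$bp, 1L)]
  }
  if (!identical(sel$dna_part, "all"))
    keep <- keep & !is.na(a$dna_part) & a$dna_part == sel$dna_part
  if (!identical(sel$segment, "all")) {
    is_hist <- role_type(a$role) %in% c("H3", "H4", "H2A", "H2B")
    keep <- keep & is_hist &
      (if (sel$segment == "tail") a$tail else !a$tail)
  }
  if (!is.null(sel$subdomain))
    keep <- keep & !is.na(a$subdomain) & a$subdomain %in% sel$subdomain
  if (!is.null(sel$bp))
    keep <- keep & !is.na(a$bp) & a$bp %in% sel$bp
  if (!is.null(sel$elety))
    keep <- keep & a$elety %in% sel$elety
  which(keep)
}
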