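## Deterministic Colvars-style configuration export for bias protocols,
## plus a parser for the same dialect (round-trip tested).

sel_to_text <- function(sel) {
  if (is.numeric(sel)) return(paste("indices", paste(sel, collapse = " ")))
  parts <- character(0)
  if (!is.null(sel$roles))
    parts <- c(parts, paste0("roles=", paste(sel$roles, collapse = "+")))
  if (!is.null(sel$dna_region))
    parts <- c(parts, paste0("region=", sel$dna_region))
  if (!identical(sel$dna_part, "all"))
    parts <- c(parts, paste0("part=", sel$dna_part))
  if (!identical(sel$segment, "all"))
    parts <- c(parts, paste0("segment=", sel$segment))
  if (!is.null(sel$subdomain))
    parts <- c(parts, paste0("subdomain=", sel$subdomain))
  if (!is.null(sel$elety))
    parts <- c(parts, paste0("atoms=", paste(sel$elety, collapse = "+")))
  paste(parts, collapse = " ")
}

text_to_sel <- function(txt) {
  txt <- trimws(txt)
  if (startsWith(txt, "indices "))
    return(as.integer(strsplit(sub("^indices ", "", txt), " ")[[1L]]))
  kv <- strsplit(strsplit(txt, " +")[[1L]], "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    val <- strsplit(p[2L], "+", fixed = TRUE)[[1L]]
    switch(p[1L],
           roles = { args$roles <- val },
           region = { args$dna_region <- val },
           part = { args$dna_part <- val },
           segment = { args$segment <- val },
           subdomain = { args$subdomain <- val },
           atoms = { args$elety <- val },
           stop("unknown selection key: ", p[1L]))
  }
  do.call(atom_selection, args)
}

fmt_num <- function(x) {
  ## deterministic number formatting: integers bare, else up to 6 signif
  if (x == round(x)) sprintf("%d", as.integer(round(x)))
  else sub("0+$", "", sprintf("%.6f", x))
}

cv_block <- function(name, variable) {
  if (inherits(variable, "nuc_distance_inv_spec")) {
    c(sprintf("colvar {"),
      sprintf("    name %s", name),
      sprintf("    distanceInv {"),
      sprintf("        exponent %d", variable$n),
      sprintf("        group1 { %s }", sel_to_text(variable$group1)),
      sprintf("        group2 { %s }", sel_to_text(variable$group2)),
      sprintf("    }"),
      sprintf("}"))
  } else if (inherits(variable, "nuc_coordination_spec")) {
    c(sprintf("colvar {"),
      sprintf("    name %s", name),
      sprintf("    coordNum {"),
      sprintf("        cutoff %s", fmt_num(variable$d0)),
      sprintf("        expNumer %d", variable$n),
      sprintf("        expDenom %d", variable$m),
      sprintf("        group1 { %s }", sel_to_text(variable$group1)),
      sprintf("        group2 { %s }", sel_to_text(variable$group2)),
      sprintf("    }"),
      sprintf("}"))
  } else stop("unsupported collective-variable kind")
}

#' Export a bias protocol as Colvars-style configuration text
#'
#' Deterministic text in the biasing dialect of common MD engines: one
#' `colvar` block per term's variable, followed by a `harmonicWalls` or
#' moving-center `harmonic` block carrying the protocol's numbers.
#'
#' @param protocol A `nuc_bias_protocol`.
#' @param path Optional file to write to.
#' @return The configuration as a single string (invisibly if `path`
#'   given).
#' @export
export_bias_config <- function(protocol, path = NULL) {
  lines <- c(sprintf("# colvars bias protocol: %s", protocol$name))
  for (tn in names(protocol$terms)) {
    term <- protocol$terms[[tn]]
    cvname <- paste0("cv_", tn)
    lines <- c(lines, "", cv_block(cvname, term$variable))
    if (inherits(term, "nuc_wall_spec")) {
      blk <- c("harmonicWalls {",
               sprintf("    name %s", tn),
               sprintf("    colvars { %s }", cvname),
               sprintf("    forceConstant %s", fmt_num(term$k)))
      if (!is.null(term$lower))
        blk <- c(blk, sprintf("    lowerWalls %s", fmt_num(term$lower)))
      if (!is.null(term$upper))
        blk <- c(blk, sprintf("    upperWalls %s", fmt_num(term$upper)))
      blk <- c(blk, "}")
    } else {
      blk <- c("harmonic {",
               sprintf("    name %s", tn),
               sprintf("    colvars { %s }", cvname),
               sprintf("    forceConstant %s", fmt_num(term$k)),
               sprintf("    centers %s", fmt_num(term$from)),
               sprintf("    targetCenters %s", fmt_num(term$to)),
               sprintf("    targetTime %s", fmt_num(term$duration)),
               "}")
    }
    lines <- c(lines, blk)
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

## --- parser for the dialect above ------------------------------------

tokenize_blocks <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  blocks <- list(); i <- 1L
  while (i <= length(lines)) {
    hdr <- trimws(lines[i])
    kind <- sub("\\s*\\{$", "", hdr)
    depth <- 1L; body <- character(0); i <- i + 1L
    while (i <= length(lines) && depth > 0L) {
      l <- lines[i]
      depth <- depth + lengths(regmatches(l, gregexpr("\\{", l))) -
        lengths(regmatches(l, gregexpr("\\}", l)))
      if (depth > 0L) body <- c(body, l)
      i <- i + 1L
    }
    blocks[[length(blocks) + 1L]] <- list(kind = kind, body = body)
  }
  blocks
}

body_field <- function(body, key) {
  ln <- grep(sprintf("^\\s*%s\\s", key), body, value = TRUE)
  if (!length(ln)) return(NULL)
  trimws(sub(sprintf("^\\s*%s\\s+", key), "", ln[1L]))
}

body_group <- function(body, key) {
  ln <- grep(sprintf("^\\s*%s\\s*\\{", key), body, value = TRUE)[1L]
  text_to_sel(sub("\\}\\s*$", "", sub(sprintf("^\\s*%s\\s*\\{\\s*", key), "", ln)))
}

parse_cv <- function(body) {
  name <- body_field(body, "name")
  sub_ln <- grep("^\\s*(distanceInv|coordNum)\\s*\\{", body)
  kind <- trimws(sub("\\s*\\{.*$", "", body[sub_ln]))
  inner <- body[(sub_ln + 1L):(length(body) - 1L)]
  if (kind == "distanceInv") {
    v <- distance_inv_spec(body_group(inner, "group1"),
                           body_group(inner, "group2"),
                           n = as.integer(body_field(inner, "exponent")))
  } else {
    v <- coordination_spec(body_group(inner, "group1"),
                           body_group(inner, "group2"),
                           d0 = as.numeric(body_field(inner, "cutoff")),
                           n = as.integer(body_field(inner, "expNumer")),
                           m = as.integer(body_field(inner, "expDenom")))
  }
  list(name = name, variable = v)
}

#' Parse a Colvars-style configuration produced by [export_bias_config()]
#'
#' @param text Configuration text (single string or lines), or a file path
#'   ending in `.colvars`/`.in`/`.txt`.
#' @return A `nuc_bias_protocol`.
#' @export
parse_bias_config <- function(text) {
  if (length(text) == 1L && file.exists(text) &&
      grepl("\\.(colvars|in|txt)$", text))
    text <- readLines(text)
  if (length(text) == 1L) text <- strsplit(text, "\n")[[1L]]
  pname <- sub("^# colvars bias protocol: ", "",
               grep("^# colvars bias protocol:", text, value = TRUE)[1L])
  if (is.na(pname)) pname <- "protocol"
  blocks <- tokenize_blocks(text)
  cvs <- list(); terms <- list()
  for (b in blocks) {
    if (b$kind == "colvar") {
      cv <- parse_cv(b$body)
      cvs[[cv$name]] <- cv$variable
    } else if (b$kind == "harmonicWalls") {
      nm <- body_field(b$body, "name")
      cvn <- gsub("[{} ]", "", body_field(b$body, "colvars"))
      lw <- body_field(b$body, "lowerWalls")
      up <- body_field(b$body, "upperWalls")
      terms[[nm]] <- harmonic_wall_spec(
        cvs[[cvn]],
        lower = if (is.null(lw)) NULL else as.numeric(lw),
        upper = if (is.null(up)) NULL else as.numeric(up),
        k = as.numeric(body_field(b$body, "forceConstant")), name = nm)
    } else if (b$kind == "harmonic") {
      nm <- body_field(b$body, "name")
      cvn <- gsub("[{} ]", "", body_field(b$body, "colvars"))
      terms[[nm]] <- steered_spec(
        cvs[[cvn]],
        from = as.numeric(body_field(b$body, "centers")),
        to = as.numeric(body_field(b$body, "targetCenters")),
        duration = as.numeric(body_field(b$body, "targetTime")),
        k = as.numeric(body_field(b$body, "forceConstant")), name = nm)
    } else stop("unknown block kind: ", b$kind)
  }
  if (!length(terms)) {
    return(structure(list(name = pname, terms = list()),
                     class = "nuc_bias_protocol"))
  }
  bias_protocol(terms, name = pname)
}
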