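# Structure input/output: PDB parsing (via bio3d), cleaning, entity typing
# and a PDB writer used to emit alanine-variant structures and fixtures.

#' Parse a protein-RNA complex from a PDB file
#'
#' Reads a PDB-format coordinate file into the package's internal structure
#' model. All models of an NMR ensemble are retained at this stage (see
#' [clean_structure()] for reduction to model 1). Chains are typed by their
#' residue content: a chain is `rna` if more than half of its non-water
#' residues map to ribonucleotides, `protein` if more than half map to amino
#' acids, and `other` otherwise (an exact 50/50 split is `other`).
#'
#' @param path path to a PDB-format file.
#' @param require_complex if `TRUE` (default) an error is raised unless the
#'   file contains at least one protein and one RNA chain.
#' @return an object of class `rnp_structure`: a list with elements
#'   `id`, `method` (`"xray"`, `"nmr"` or `"other"`), `resolution` (Angstrom,
#'   `NA` if absent), `n_models`, `atoms` (data.frame of heavy and hydrogen
#'   atoms of model 1), `models` (list of coordinate matrices, one per
#'   model), `entities` (named character vector chain -> entity) and
#'   `cleaned` flag.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_pdb(make_complex(fixture_spec(seed = 1)), pdb)
#' s <- parse_structure(pdb)
#' s$entities
parse_structure <- function(path, require_complex = TRUE) {
  if (!file.exists(path) || dir.exists(path)) {
    stop("cannot read PDB file: ", path)
  }
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L) {
    stop("parse error in ", path, ": file is empty (line 1)")
  }
  n_atom_lines <- sum(startsWith(txt, "ATOM") | startsWith(txt, "HETATM"))
  if (n_atom_lines == 0L) {
    first_bad <- which(!startsWith(txt, "REMARK"))[1]
    stop("parse error in ", path, ": no ATOM/HETATM records (line ",
         ifelse(is.na(first_bad), 1L, first_bad), ")")
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e))
    }
  )

  at <- pdb$atom
  atoms <- data.frame(
    record = at$type,
    eleno = at$eleno,
    elety = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resnum = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = guess_element(at$elesy, at$elety),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad) > 0) {
    stop("parse error in ", path, ": non-finite coordinates at atom serial ",
         atoms$eleno[bad[1]])
  }
  cls <- classify_resname(atoms$resname)
  atoms$kind <- cls$kind
  atoms$standard_parent <- cls$standard_parent
  atoms$is_modified <- cls$is_modified

  n_models <- max(1L, nrow(pdb$xyz))
  models <- lapply(seq_len(n_models), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })

  hdr <- parse_pdb_header(txt)
  s <- structure(list(
    id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
    method = hdr$method,
    resolution = hdr$resolution,
    n_models = n_models,
    atoms = atoms,
    models = models,
    cleaned = FALSE
  ), class = "rnp_structure")
  s$entities <- chain_entities(s)

  if (require_complex) {
    ent <- s$entities
    if (!any(ent == "protein") || !any(ent == "rna")) {
      stop("not a protein–RNA complex: file ", path, " has ",
           sum(ent == "protein"), " protein and ", sum(ent == "rna"),
           " RNA chain(s)")
    }
  }
  s
}

# EXPDTA / REMARK 2 header fields; tolerant of absent headers.
#' @keywords internal
parse_pdb_header <- function(txt) {
  method <- "other"
  expdta <- grep("^EXPDTA", txt, value = TRUE)
  if (length(expdta) > 0) {
    if (grepl("X-RAY", expdta[1], ignore.case = TRUE)) method <- "xray"
    else if (grepl("NMR", expdta[1], ignore.case = TRUE)) method <- "nmr"
  }
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", txt, value = TRUE)
  if (length(rem2) > 0) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m) == 1) resolution <- as.numeric(m)
  }
  list(method = method, resolution = resolution)
}

# Element symbol: use the PDB element column when present, otherwise fall
# back to the first letter of the atom name (digits and primes stripped).
#' @keywords internal
guess_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z]", "", elety[miss])
    el[miss] <- toupper(substr(nm, 1, 1))
  }
  el
}

#' Entity type of each chain
#'
#' @param s an `rnp_structure`.
#' @return named character vector mapping chain id to `"protein"`, `"rna"`
#'   or `"other"`.
#' @export
chain_entities <- function(s) {
  stopifnot(inherits(s, "rnp_structure"))
  at <- s$atoms[!(s$atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  chains <- sort(unique(at$chain))
  ent <- vapply(chains, function(ch) {
    res <- unique(at[at$chain == ch, c("resnum", "icode", "kind")])
    n <- nrow(res)
    if (n == 0) return("other")
    f_aa <- sum(res$kind == "amino_acid") / n
    f_nt <- sum(res$kind == "nucleotide") / n
    if (f_nt > 0.5) "rna" else if (f_aa > 0.5) "protein" else "other"
  }, character(1))
  names(ent) <- chains
  ent
}

#' Clean a parsed structure
#'
#' Reduces a structure to the form used by all downstream analyses: keeps
#' model 1 only (NMR ensembles are represented by their first conformer),
#' drops hydrogens/deuteriums and waters, keeps the highest-occupancy
#' alternate location per atom (ties resolved by file order), and annotates
#' modified polymer residues with their canonical parent via a built-in
#' table. Cleaning is total and idempotent.
#'
#' @param s an `rnp_structure` from [parse_structure()].
#' @return a cleaned `rnp_structure` with a single model.
#' @export
clean_structure <- function(s) {
  stopifnot(inherits(s, "rnp_structure"))
  at <- s$atoms

  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resname %in% WATER_RESNAMES), , drop = FALSE]

  # highest-occupancy altloc per (chain, residue, atom name); tie -> first
  if (any(at$altloc != "")) {
    key <- paste(at$chain, at$resnum, at$icode, at$elety, sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -at$occupancy,
                 seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resnum, at$icode, at$elety,
                               sep = "\r")), , drop = FALSE]
    at <- at[order(match(at$eleno, s$atoms$eleno)), , drop = FALSE]
    at$altloc <- ""
  }
  rownames(at) <- NULL

  out <- s
  out$atoms <- at
  out$models <- NULL
  out$n_models <- 1L
  out$cleaned <- TRUE
  out$entities <- chain_entities(out)
  out
}

#' Fraction of modified nucleotides
#'
#' Counts modified nucleotides (e.g. pseudouridine, methylated bases) as a
#' fraction of all nucleotides, per RNA chain and overall. Used by the
#' dataset-curation filter that discards entries whose RNA carries more
#' than 50 percent modified nucleobases.
#'
#' @param s a cleaned `rnp_structure` with at least one RNA chain.
#' @return list with `overall` (fraction in \[0, 1\]) and `per_chain`
#'   (named numeric vector).
#' @export
modified_base_fraction <- function(s) {
  stopifnot(inherits(s, "rnp_structure"))
  rna_chains <- names(s$entities)[s$entities == "rna"]
  if (length(rna_chains) == 0) stop("structure has no RNA chain")
  at <- s$atoms[s$atoms$chain %in% rna_chains & s$atoms$kind == "nucleotide", ]
  res <- unique(at[, c("chain", "resnum", "icode", "is_modified")])
  per_chain <- vapply(rna_chains, function(ch) {
    r <- res[res$chain == ch, ]
    if (nrow(r) == 0) return(NA_real_)
    mean(r$is_modified)
  }, numeric(1))
  list(overall = mean(res$is_modified), per_chain = per_chain)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM/HETATM records (model 1), with TER
#' records at chain ends. Coordinates are written at PDB precision
#' (3 decimals), so a parse -> write -> parse round trip preserves heavy
#' atom coordinates exactly at that precision.
#'
#' @param s an `rnp_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "rnp_structure"))
  at <- s$atoms
  lines <- character(0)
  if (s$method == "xray") {
    lines <- c(lines, "EXPDTA    X-RAY DIFFRACTION")
    if (!is.na(s$resolution)) {
      lines <- c(lines, sprintf(
        "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", s$resolution))
    }
  } else if (s$method == "nmr") {
    lines <- c(lines, "EXPDTA    SOLUTION NMR")
  }
  serial <- 0L
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(ca[i, ], serial))
    }
    serial <- serial + 1L
    last <- ca[nrow(ca), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s", serial,
                              last$resname, last$chain, last$resnum,
                              ifelse(last$icode == "", " ", last$icode)))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' @keywords internal
format_pdb_atom <- function(a, serial) {
  record <- if (identical(a$record, "HETATM")) "HETATM" else "ATOM  "
  name <- a$elety
  # atom names shorter than 4 chars start in column 14
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, name_fmt,
          ifelse(a$altloc == "", " ", a$altloc),
          a$resname, a$chain, a$resnum,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, 0,
          substr(a$element, 1, 2))
}

#' @export
print.rnp_structure <- function(x, ...) {
  ent <- x$entities
  cat("<rnp_structure> ", x$id, "\n", sep = "")
  cat("  method: ", x$method,
      if (!is.na(x$resolution)) sprintf(" (%.2f A)", x$resolution), "\n",
      sep = "")
  cat("  models: ", x$n_models, if (x$cleaned) "  [cleaned]", "\n", sep = "")
  for (ch in names(ent)) {
    n_res <- nrow(unique(x$atoms[x$atoms$chain == ch,
                                 c("resnum", "icode")]))
    cat(sprintf("  chain %s: %s, %d residues\n", ch, ent[ch], n_res))
  }
  invisible(x)
}

# residue-level view of a structure's atoms: one row per residue
#' @keywords internal
residue_table <- function(s, chains = NULL) {
  at <- s$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  u <- !duplicated(paste(at$chain, at$resnum, at$icode, sep = "\r"))
  at[u, c("chain", "resnum", "icode", "resname", "kind",
          "standard_parent", "is_modified")]
}

# atoms of one residue
#' @keywords internal
residue_atoms <- function(s, chain, resnum, icode = "") {
  at <- s$atoms
  at[at$chain == chain & at$resnum == resnum & at$icode == icode, ,
     drop = FALSE]
}
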