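# Computational alanine scanning: truncate each interface amino acid to
# alanine, score wild type and variant with the knowledge-based potential,
# convert the score change to delta-ln values and normalise them per
# interface to dimensionless interaction scores (IS). Residues with IS > 2
# are hotspots, 1 < IS <= 2 warmspots.

ALA_KEPT_ATOMS <- c("N", "CA", "C", "O", "OXT", "CB")
NOT_VARIED <- c("GLY", "PRO", "ALA")

#' Truncate one residue to alanine
#'
#' Produces a new structure in which the target residue keeps exactly the
#' backbone atoms (N, CA, C, O, OXT if present) plus CB and is renamed
#' ALA. A missing CB is rebuilt at ideal tetrahedral geometry, 1.52 A from
#' CA, from the N/CA/C positions. Every other residue is untouched.
#'
#' @param s a cleaned `rnp_structure`.
#' @param chain,resnum,icode identify the residue to truncate.
#' @return a new `rnp_structure`.
#' @export
mutate_to_alanine <- function(s, chain, resnum, icode = "") {
  stopifnot(inherits(s, "rnp_structure"))
  at <- s$atoms
  sel <- at$chain == chain & at$resnum == resnum & at$icode == icode
  if (!any(sel)) stop("residue ", chain, resnum, icode, " not found")
  res <- at[sel, , drop = FALSE]
  if (res$kind[1] != "amino_acid") {
    stop("cannot truncate a non-amino-acid residue to alanine")
  }
  if (res$standard_parent[1] %in% NOT_VARIED) {
    stop(res$standard_parent[1], " is not varied in alanine scanning")
  }
  keep <- sel & at$elety %in% ALA_KEPT_ATOMS
  out <- s
  out$atoms <- at[!sel | keep, , drop = FALSE]
  mut <- out$atoms$chain == chain & out$atoms$resnum == resnum &
    out$atoms$icode == icode
  out$atoms$resname[mut] <- "ALA"
  out$atoms$standard_parent[mut] <- "ALA"
  out$atoms$is_modified[mut] <- FALSE
  if (!any(out$atoms$elety[mut] == "CB")) {
    cb <- ideal_cb(res)
    row <- out$atoms[which(mut)[1], , drop = FALSE]
    row$elety <- "CB"
    row$element <- "C"
    row[, c("x", "y", "z")] <- as.list(cb)
    out$atoms <- rbind(out$atoms[seq_len(max(which(mut))), ], row,
                       out$atoms[-seq_len(max(which(mut))), ])
  }
  rownames(out$atoms) <- NULL
  out$models <- NULL
  out
}

# ideal tetrahedral CB position from backbone N/CA/C
#' @keywords internal
ideal_cb <- function(res_atoms) {
  get1 <- function(nm) {
    a <- res_atoms[res_atoms$elety == nm, c("x", "y", "z")]
    if (nrow(a) < 1) stop("cannot rebuild CB: backbone atom ", nm,
                          " missing")
    as.numeric(a[1, ])
  }
  n <- get1("N"); ca <- get1("CA"); cc <- get1("C")
  b1 <- unit(n - ca)
  b2 <- unit(cc - ca)
  bis <- unit(b1 + b2)
  perp <- unit(pracma_cross(b1, b2))
  ca + 1.52 * unit(-bis * 0.577 + perp * 0.817)
}

#' Normalise delta-ln values to per-interface interaction scores
#'
#' Divides each non-negative delta-ln value by the mean of the non-negative
#' values of the same interface. Negative or missing entries (excluded
#' variants) get `NA`. By construction the mean of the returned scores over
#' non-excluded residues equals 1.
#'
#' @param delta_ln numeric vector of per-residue delta-ln values; `NA`
#'   marks unscorable residues.
#' @return numeric vector of interaction scores, `NA` where excluded.
#' @export
#' @examples
#' interaction_scores(c(0.2, 0.4, 0.6))  # 0.5, 1.0, 1.5
interaction_scores <- function(delta_ln) {
  keep <- !is.na(delta_ln) & delta_ln >= 0
  if (!any(keep)) {
    stop("no non-negative delta-ln values; interaction scores undefined")
  }
  mean_delta <- mean(delta_ln[keep])
  if (mean_delta == 0) {
    stop("all delta-ln values are zero; interaction scores undefined")
  }
  out <- rep(NA_real_, length(delta_ln))
  out[keep] <- delta_ln[keep] / mean_delta
  out
}

#' Classify a normalised interaction score
#'
#' `IS > 2` is a hotspot; `1 < IS <= 2` a warmspot; `IS <= 1` other.
#'
#' @param is_value non-negative numeric vector of interaction scores.
#' @return character vector of classes.
#' @export
classify_spot <- function(is_value) {
  if (any(is.na(is_value)) || any(is_value < 0)) {
    stop("interaction scores must be non-negative ",
         "(negative delta-ln values are excluded upstream)")
  }
  ifelse(is_value > 2, "hotspot",
         ifelse(is_value > 1, "warmspot", "other"))
}

#' Alanine-scan a protein-RNA interface
#'
#' For every protein residue with a heavy atom within `cutoff` of the RNA
#' (glycine, proline and alanine excepted), the complex is rescored with
#' that residue truncated to alanine and the score change expressed as
#' `delta_ln = ln|DARS_WT| - ln|DARS_Ala|`. Residues with negative
#' delta-ln (side chains stabilising intramolecular rather than interface
#' contacts) are excluded; the remaining values are divided by their
#' interface mean, giving interaction scores (IS) that average exactly 1
#' per interface. Wild-type and variant scores differ only in pair terms
#' of the mutated residue, so variants are scored incrementally from the
#' wild-type pair sum.
#'
#' @param s a cleaned `rnp_structure`.
#' @param m an `rnp_potential`; default [default_model()].
#' @param protein_chains,rna_chains chain selection defining the interface
#'   (one scan per selected pairing; no symmetry averaging).
#' @param cutoff interface cutoff in Angstrom (default 7).
#' @return object of class `interface_scan`: list with `records`
#'   (data.frame: chain, resnum, icode, resname, dars_wt, dars_ala,
#'   delta_ln, is, class), `mean_delta`, `n_positive`, `dars_wt`,
#'   `protein_chains`, `rna_chains`, `cutoff`.
#' @export
alanine_scan <- function(s, m = default_model(), protein_chains = NULL,
                         rna_chains = NULL, cutoff = 7.0) {
  stopifnot(inherits(s, "rnp_structure"), inherits(m, "rnp_potential"))
  protein_chains <- select_entity_chains(s, protein_chains, "protein")
  rna_chains <- select_entity_chains(s, rna_chains, "rna")

  iface_all <- interface_residues(s, cutoff = cutoff, exclude = character(0),
                                  protein_chains = protein_chains,
                                  rna_chains = rna_chains)
  scanned <- iface_all[!(iface_all$parent %in% NOT_VARIED) &
                         iface_all$parent != "", , drop = FALSE]
  not_varied <- iface_all[iface_all$parent %in% NOT_VARIED, , drop = FALSE]

  cen <- interaction_centers(s, protein_chains, rna_chains)
  cp <- cen$protein; cr <- cen$rna
  wt <- score_centers(cp, cr, m)
  dars_wt <- wt$dars

  n <- nrow(scanned)
  rec <- data.frame(
    chain = scanned$chain, resnum = scanned$resnum, icode = scanned$icode,
    resname = scanned$resname, dars_wt = rep(dars_wt, n),
    dars_ala = NA_real_, delta_ln = NA_real_, is = NA_real_,
    class = NA_character_, stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    rows <- cp$chain == scanned$chain[k] & cp$resnum == scanned$resnum[k] &
      cp$icode == scanned$icode[k]
    old <- cp[rows, , drop = FALSE]
    new <- alanine_centers(s, old, scanned[k, ])
    d_old <- score_centers(old, cr, m)$dars
    d_new <- score_centers(new, cr, m)$dars
    rec$dars_ala[k] <- dars_wt - d_old + d_new
  }

  scorable <- rec$dars_wt != 0 & rec$dars_ala != 0
  if (n > 0 && !any(scorable)) {
    stop("all interface residues are unscorable (zero complex scores)")
  }
  if (any(!scorable)) {
    warning(sum(!scorable), " residue(s) unscorable (zero score); ",
            "excluded from normalisation")
  }
  rec$delta_ln[scorable] <- log(abs(rec$dars_wt[scorable])) -
    log(abs(rec$dars_ala[scorable]))

  pos <- scorable & rec$delta_ln >= 0
  n_positive <- sum(pos)
  if (n == 0 || n_positive == 0) {
    stop("no residues with non-negative delta-ln; interface cannot be ",
         "normalised")
  }
  mean_delta <- mean(rec$delta_ln[pos])
  rec$is <- interaction_scores(rec$delta_ln)
  rec$class[pos] <- classify_spot(rec$is[pos])
  rec$class[scorable & rec$delta_ln < 0] <- "excluded_negative"
  rec$class[!scorable] <- "unscorable"

  if (nrow(not_varied) > 0) {
    rec <- rbind(rec, data.frame(
      chain = not_varied$chain, resnum = not_varied$resnum,
      icode = not_varied$icode, resname = not_varied$resname,
      dars_wt = dars_wt, dars_ala = NA_real_, delta_ln = NA_real_,
      is = NA_real_, class = "not_varied", stringsAsFactors = FALSE))
  }
  rec <- rec[order(rec$chain, rec$resnum, rec$icode), ]
  rownames(rec) <- NULL

  structure(list(records = rec, mean_delta = mean_delta,
                 n_positive = n_positive, dars_wt = dars_wt,
                 protein_chains = protein_chains, rna_chains = rna_chains,
                 cutoff = cutoff),
            class = "interface_scan")
}

# interaction centers of a residue after truncation to alanine:
# backbone CA kept (type ALA), side-chain center collapses to CB
#' @keywords internal
alanine_centers <- function(s, old_centers, res_row) {
  if (nrow(old_centers) == 0) return(old_centers)
  at <- residue_atoms(s, res_row$chain, res_row$resnum, res_row$icode)
  cb <- at[at$elety == "CB", c("x", "y", "z")]
  cb <- if (nrow(cb) >= 1) as.numeric(cb[1, ]) else ideal_cb(at)
  new <- old_centers
  new$restype <- "ALA"
  sc <- new$class == "sidechain"
  if (any(sc)) {
    new[sc, c("x", "y", "z")] <- as.list(cb)
  } else {
    row <- new[new$class == "backbone", , drop = FALSE][1, ]
    row$class <- "sidechain"
    row[, c("x", "y", "z")] <- as.list(cb)
    new <- rbind(new, row)
  }
  new
}

#' @export
print.interface_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("interface scan: %d residue(s), protein %s vs RNA %s\n",
              nrow(r), paste(x$protein_chains, collapse = ","),
              paste(x$rna_chains, collapse = ",")))
  cat(sprintf("  DARS_WT %.4f; %d non-negative delta-ln (mean %.4f)\n",
              x$dars_wt, x$n_positive, x$mean_delta))
  cat(sprintf("  hotspots: %d, warmspots: %d, excluded (negative): %d\n",
              sum(r$class == "hotspot", na.rm = TRUE),
              sum(r$class == "warmspot", na.rm = TRUE),
              sum(r$class == "excluded_negative", na.rm = TRUE)))
  invisible(x)
}

#' Correlate interaction scores with experimental ddG values
#'
#' Matches scan records to a user-supplied table of experimental alanine
#' mutagenesis ddG values and reports the Pearson correlation. At least 3
#' matched pairs are required; fewer than 5 triggers a warning (per the
#' convention of requiring at least five pairs per complex for a
#' meaningful per-interface correlation).
#'
#' @param result an `interface_scan`.
#' @param ddg data.frame with columns `chain`, `resnum`, optional `icode`,
#'   and `ddg` (kcal/mol).
#' @return list with `r` (Pearson correlation), `n_pairs`, and the matched
#'   data.frame `pairs`.
#' @export
correlate_with_ddg <- function(result, ddg) {
  stopifnot(inherits(result, "interface_scan"), is.data.frame(ddg))
  if (!all(c("chain", "resnum", "ddg") %in% names(ddg))) {
    stop("ddg table needs columns chain, resnum, ddg")
  }
  if (is.null(ddg$icode)) ddg$icode <- ""
  rec <- result$records
  rec <- rec[!is.na(rec$is), , drop = FALSE]
  key_rec <- paste(rec$chain, rec$resnum, rec$icode, sep = "\r")
  key_ddg <- paste(ddg$chain, ddg$resnum, ddg$icode, sep = "\r")
  idx <- match(key_ddg, key_rec)
  ok <- !is.na(idx)
  pairs <- data.frame(chain = ddg$chain[ok], resnum = ddg$resnum[ok],
                      is = rec$is[idx[ok]], ddg = ddg$ddg[ok],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3) {
    stop("need at least 3 matched residue pairs, got ", nrow(pairs))
  }
  if (nrow(pairs) < 5) {
    warning("fewer than 5 matched pairs; correlation is fragile")
  }
  if (sd(pairs$is) == 0 || sd(pairs$ddg) == 0) {
    stop("zero variance in matched scores; correlation undefined")
  }
  list(r = cor(pairs$is, pairs$ddg), n_pairs = nrow(pairs), pairs = pairs)
}

#' Write a scan result as TSV
#'
#' Tab-separated records preceded by comment header lines carrying the
#' package version, chain selection and cutoff.
#'
#' @param result an `interface_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path) {
  stopifnot(inherits(result, "interface_scan"))
  hdr <- c(
    sprintf("# AlaScanRNP %s",
            as.character(utils::packageVersion("AlaScanRNP"))),
    sprintf("# protein_chains=%s rna_chains=%s cutoff=%.1f",
            paste(result$protein_chains, collapse = ","),
            paste(result$rna_chains, collapse = ","), result$cutoff),
    sprintf("# dars_wt=%.6f mean_delta=%.6f n_positive=%d",
            result$dars_wt, result$mean_delta, result$n_positive)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(result$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
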