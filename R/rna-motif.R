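# Base-pair detection and classification of the bound RNA into the four
# structural motif classes: single strand (ssRNA), duplex (dsRNA), hairpin
# (hpRNA) and complex fold (compRNA).

# Watson-Crick face atom: N1 for purines, N3 for pyrimidines.
#' @keywords internal
wc_face_atom <- function(parent) {
  ifelse(parent %in% c("A", "G"), "N1", "N3")
}

#' @keywords internal
is_wc_sequence_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Detect RNA base pairs geometrically
#'
#' Two nucleotides are considered paired when (a) their C1'-C1' distance
#' lies in \[8.9, 11.9\] Angstrom, (b) the distance between their
#' Watson-Crick face atoms (purine N1, pyrimidine N3) is at most
#' `wc_cutoff`, and (c) their base planes are roughly coplanar (angle
#' between plane normals at most `coplanar_deg` degrees, or at least
#' 180 - `coplanar_deg`). Each base is matched to at most one partner,
#' greedily by shortest Watson-Crick face distance. Pairs with a
#' complementary sequence (A-U, G-C) are typed `"WC"`, other geometric
#' pairs `"other"`.
#'
#' @param s a cleaned `rnp_structure` containing RNA.
#' @param c1_range allowed C1'-C1' distance range (Angstrom).
#' @param wc_cutoff maximal WC-face heavy-atom distance (Angstrom).
#' @param coplanar_deg base-plane coplanarity tolerance (degrees).
#' @return data.frame with one row per pair: `chain_i`, `resnum_i`,
#'   `chain_j`, `resnum_j`, `parent_i`, `parent_j`, `type`, `interchain`,
#'   `wc_distance`; pairs listed once with (i, j) in chain/number order.
#' @export
detect_base_pairs <- function(s, c1_range = c(8.9, 11.9), wc_cutoff = 3.5,
                              coplanar_deg = 35) {
  stopifnot(inherits(s, "rnp_structure"))
  nt <- residue_table(s)
  nt <- nt[nt$kind == "nucleotide", , drop = FALSE]
  empty <- data.frame(chain_i = character(0), resnum_i = integer(0),
                      chain_j = character(0), resnum_j = integer(0),
                      parent_i = character(0), parent_j = character(0),
                      type = character(0), interchain = logical(0),
                      wc_distance = numeric(0))
  if (nrow(nt) < 2) return(empty)

  # per-nucleotide geometry: C1', WC atom, base-plane normal
  geo <- vector("list", nrow(nt))
  for (k in seq_len(nrow(nt))) {
    at <- residue_atoms(s, nt$chain[k], nt$resnum[k], nt$icode[k])
    c1 <- at[at$elety %in% c("C1'", "C1*"), c("x", "y", "z")]
    parent <- nt$standard_parent[k]
    wc_name <- if (parent == "") "N1" else wc_face_atom(parent)
    wc <- at[at$elety == wc_name, c("x", "y", "z")]
    base_at <- at[rna_moiety(at$elety) == "base", c("x", "y", "z")]
    if (nrow(c1) != 1 || nrow(wc) != 1 || nrow(base_at) < 3) next
    geo[[k]] <- list(c1 = as.numeric(c1[1, ]), wc = as.numeric(wc[1, ]),
                     normal = plane_normal(as.matrix(base_at)))
  }
  ok <- !vapply(geo, is.null, logical(1))
  nt <- nt[ok, , drop = FALSE]
  geo <- geo[ok]
  m <- nrow(nt)
  if (m < 2) return(empty)

  c1m <- t(vapply(geo, `[[`, numeric(3), "c1"))
  wcm <- t(vapply(geo, `[[`, numeric(3), "wc"))
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      d_c1 <- sqrt(sum((c1m[i, ] - c1m[j, ])^2))
      if (d_c1 < c1_range[1] || d_c1 > c1_range[2]) next
      d_wc <- sqrt(sum((wcm[i, ] - wcm[j, ])^2))
      if (d_wc > wc_cutoff) next
      ang <- acos(pmin(1, abs(sum(geo[[i]]$normal * geo[[j]]$normal)))) *
        180 / pi
      if (ang > coplanar_deg) next   # |cos| folds >=145 onto <=35
      cand[[length(cand) + 1]] <- c(i, j, d_wc)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  taken <- rep(FALSE, m)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!taken[i] && !taken[j]) {
      keep[r] <- TRUE
      taken[i] <- taken[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  i <- cand[, 1]; j <- cand[, 2]
  out <- data.frame(
    chain_i = nt$chain[i], resnum_i = nt$resnum[i],
    chain_j = nt$chain[j], resnum_j = nt$resnum[j],
    parent_i = nt$standard_parent[i], parent_j = nt$standard_parent[j],
    type = ifelse(is_wc_sequence_pair(nt$standard_parent[i],
                                      nt$standard_parent[j]),
                  "WC", "other"),
    interchain = nt$chain[i] != nt$chain[j],
    wc_distance = cand[, 3],
    stringsAsFactors = FALSE
  )
  swap <- order_pair_swap(out)
  out[swap, c("chain_i", "resnum_i", "chain_j", "resnum_j",
              "parent_i", "parent_j")] <-
    out[swap, c("chain_j", "resnum_j", "chain_i", "resnum_i",
                "parent_j", "parent_i")]
  out <- out[order(out$chain_i, out$resnum_i), ]
  rownames(out) <- NULL
  out
}

#' @keywords internal
order_pair_swap <- function(bp) {
  bp$chain_i > bp$chain_j |
    (bp$chain_i == bp$chain_j & bp$resnum_i > bp$resnum_j)
}

# maximal runs of >= min_len consecutive intrachain pairs
# (i, j), (i+1, j-1), ...
#' @keywords internal
find_stems <- function(bp, min_len = 3) {
  intra <- bp[!bp$interchain, , drop = FALSE]
  stems <- list()
  if (nrow(intra) == 0) return(stems)
  for (ch in unique(intra$chain_i)) {
    b <- intra[intra$chain_i == ch & intra$chain_j == ch, , drop = FALSE]
    b <- b[order(b$resnum_i), , drop = FALSE]
    run <- list(b[0, ])
    cur <- 1
    if (nrow(b) == 0) next
    run[[1]] <- b[1, , drop = FALSE]
    for (r in seq_len(nrow(b))[-1]) {
      prev <- run[[cur]][nrow(run[[cur]]), ]
      if (b$resnum_i[r] == prev$resnum_i + 1 &&
          b$resnum_j[r] == prev$resnum_j - 1) {
        run[[cur]] <- rbind(run[[cur]], b[r, ])
      } else {
        cur <- cur + 1
        run[[cur]] <- b[r, , drop = FALSE]
      }
    }
    stems <- c(stems, Filter(function(x) nrow(x) >= min_len, run))
  }
  stems
}

#' Classify the bound RNA structural motif
#'
#' Applies ordered decision rules to the geometric base-pair list:
#' if fewer than `ss_threshold` of the nucleotides are paired the RNA is a
#' single strand (`ssRNA`); if at least 60 percent of pairs are interchain
#' and they all join one chain pair it is a duplex (`dsRNA`); a single RNA
#' chain with exactly one intrachain stem (>= 3 consecutive pairs) closed
#' by an apical loop is a hairpin (`hpRNA`); anything else is a complex
#' fold (`compRNA`).
#'
#' @param s a cleaned `rnp_structure` with RNA.
#' @param ss_threshold paired-nucleotide fraction below which the RNA is
#'   called single-stranded (default 0.2).
#' @param stem_min_pairs minimal consecutive pairs forming a stem.
#' @param ... passed to [detect_base_pairs()].
#' @return list of class `motif_class` with `label`, `paired_fraction`,
#'   `n_stems`, `evidence`.
#' @export
classify_rna_motif <- function(s, ss_threshold = 0.2, stem_min_pairs = 3,
                               ...) {
  stopifnot(inherits(s, "rnp_structure"))
  rna_chains <- names(s$entities)[s$entities == "rna"]
  if (length(rna_chains) == 0) stop("structure has no RNA chain")
  rna <- subset_chains(s, rna_chains)
  nt <- residue_table(rna)
  nt <- nt[nt$kind == "nucleotide", ]
  n_nt <- nrow(nt)
  bp <- detect_base_pairs(rna, ...)
  paired_fraction <- if (n_nt > 0) 2 * nrow(bp) / n_nt else 0
  stems <- find_stems(bp, stem_min_pairs)
  n_stems <- length(stems)

  label <- NULL
  evidence <- sprintf("%d nt, %d pairs (%.0f%% interchain), %d stem(s)",
                      n_nt, nrow(bp),
                      if (nrow(bp) > 0) 100 * mean(bp$interchain) else 0,
                      n_stems)
  if (paired_fraction < ss_threshold) {
    label <- "ssRNA"
  } else if (nrow(bp) > 0 && mean(bp$interchain) >= 0.6 &&
             one_duplex(bp)) {
    label <- "dsRNA"
  } else if (length(rna_chains) == 1 && n_stems == 1 &&
             has_apical_loop(stems[[1]])) {
    label <- "hpRNA"
  } else {
    label <- "compRNA"
  }
  structure(list(label = label, paired_fraction = paired_fraction,
                 n_stems = n_stems, evidence = evidence),
            class = "motif_class")
}

# all interchain pairs join the same (unordered) chain pair
#' @keywords internal
one_duplex <- function(bp) {
  inter <- bp[bp$interchain, , drop = FALSE]
  if (nrow(inter) == 0) return(FALSE)
  key <- paste(pmin(inter$chain_i, inter$chain_j),
               pmax(inter$chain_i, inter$chain_j))
  length(unique(key)) == 1
}

# innermost pair of the stem encloses >= 2 unpaired nucleotides
#' @keywords internal
has_apical_loop <- function(stem) {
  innermost <- stem[nrow(stem), ]
  (innermost$resnum_j - innermost$resnum_i - 1) >= 2
}

#' @export
print.motif_class <- function(x, ...) {
  cat(sprintf("RNA motif: %s (paired fraction %.2f; %s)\n",
              x$label, x$paired_fraction, x$evidence))
  invisible(x)
}
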