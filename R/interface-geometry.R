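# Interface characterisation: heavy-atom contacts at a distance cutoff,
# moiety partitioning, solvent-accessible and buried surface area, and the
# per-complex residue/nucleotide frequency statistics.

#' Subset a structure to selected chains
#'
#' @param s an `rnp_structure`.
#' @param chains chain ids to keep.
#' @return an `rnp_structure` containing only those chains.
#' @export
subset_chains <- function(s, chains) {
  stopifnot(inherits(s, "rnp_structure"))
  missing <- setdiff(chains, unique(s$atoms$chain))
  if (length(missing) > 0) {
    stop("chain(s) not in structure: ", paste(missing, collapse = ","))
  }
  out <- s
  out$atoms <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$models <- NULL
  out$entities <- chain_entities(out)
  out
}

#' @keywords internal
select_entity_chains <- function(s, chains, entity) {
  if (is.null(chains)) {
    chains <- names(s$entities)[s$entities == entity]
  }
  if (length(chains) == 0) stop("structure has no ", entity, " chain")
  chains
}

#' Find protein-RNA heavy-atom contacts
#'
#' Enumerates all (protein atom, RNA atom) pairs within `cutoff` Angstrom
#' and annotates each with the protein moiety (backbone = N, CA, C, O, OXT;
#' everything else side chain) and the RNA moiety (phosphate = P, OP1, OP2,
#' OP3; sugar = ribose atoms including O5'/O3'; base = remaining base heavy
#' atoms).
#'
#' @param s a cleaned `rnp_structure`.
#' @param cutoff contact distance cutoff in Angstrom (default 4.0).
#' @param protein_chains,rna_chains chain selections; default all chains of
#'   the corresponding entity.
#' @return a data.frame of class `contact_table` (one row per contact) with
#'   attribute `cutoff`; zero rows if there are no contacts.
#' @export
find_contacts <- function(s, cutoff = 4.0, protein_chains = NULL,
                          rna_chains = NULL) {
  stopifnot(inherits(s, "rnp_structure"))
  protein_chains <- select_entity_chains(s, protein_chains, "protein")
  rna_chains <- select_entity_chains(s, rna_chains, "rna")

  pa <- s$atoms[s$atoms$chain %in% protein_chains &
                  s$atoms$kind == "amino_acid", , drop = FALSE]
  ra <- s$atoms[s$atoms$chain %in% rna_chains &
                  s$atoms$kind == "nucleotide", , drop = FALSE]

  empty <- data.frame(
    protein_chain = character(0), protein_resnum = integer(0),
    protein_icode = character(0), protein_resname = character(0),
    protein_parent = character(0), protein_atom = character(0),
    rna_chain = character(0), rna_resnum = integer(0),
    rna_icode = character(0), rna_resname = character(0),
    rna_parent = character(0), rna_atom = character(0),
    distance = numeric(0), protein_moiety = character(0),
    rna_moiety = character(0), stringsAsFactors = FALSE
  )
  if (nrow(pa) == 0 || nrow(ra) == 0) {
    return(structure(empty, class = c("contact_table", "data.frame"),
                     cutoff = cutoff))
  }

  d2 <- cross_dist2(as.matrix(pa[, c("x", "y", "z")]),
                    as.matrix(ra[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(structure(empty, class = c("contact_table", "data.frame"),
                     cutoff = cutoff))
  }
  i <- hit[, 1]; j <- hit[, 2]
  ct <- data.frame(
    protein_chain = pa$chain[i], protein_resnum = pa$resnum[i],
    protein_icode = pa$icode[i], protein_resname = pa$resname[i],
    protein_parent = pa$standard_parent[i], protein_atom = pa$elety[i],
    rna_chain = ra$chain[j], rna_resnum = ra$resnum[j],
    rna_icode = ra$icode[j], rna_resname = ra$resname[j],
    rna_parent = ra$standard_parent[j], rna_atom = ra$elety[j],
    distance = sqrt(d2[hit]),
    protein_moiety = protein_moiety(pa$elety[i]),
    rna_moiety = rna_moiety(ra$elety[j]),
    stringsAsFactors = FALSE
  )
  ct <- ct[order(ct$protein_chain, ct$protein_resnum, ct$protein_atom,
                 ct$rna_chain, ct$rna_resnum, ct$rna_atom), ]
  rownames(ct) <- NULL
  structure(ct, class = c("contact_table", "data.frame"), cutoff = cutoff)
}

#' Protein residues at the scanning interface
#'
#' Lists protein residues with at least one heavy atom within `cutoff`
#' Angstrom of any RNA heavy atom, excluding residue types that cannot be
#' varied to alanine (glycine, proline and alanine itself by default).
#'
#' @inheritParams find_contacts
#' @param cutoff interface cutoff in Angstrom (default 7.0, the scanning
#'   interface definition).
#' @param exclude residue codes excluded from the list.
#' @return data.frame of residues (chain, resnum, icode, resname, parent,
#'   min_distance), ordered by chain then residue number.
#' @export
interface_residues <- function(s, cutoff = 7.0,
                               exclude = c("GLY", "PRO", "ALA"),
                               protein_chains = NULL, rna_chains = NULL) {
  stopifnot(inherits(s, "rnp_structure"))
  protein_chains <- select_entity_chains(s, protein_chains, "protein")
  rna_chains <- select_entity_chains(s, rna_chains, "rna")
  pa <- s$atoms[s$atoms$chain %in% protein_chains &
                  s$atoms$kind == "amino_acid", , drop = FALSE]
  ra <- s$atoms[s$atoms$chain %in% rna_chains &
                  s$atoms$kind == "nucleotide", , drop = FALSE]
  if (nrow(pa) == 0 || nrow(ra) == 0) {
    return(data.frame(chain = character(0), resnum = integer(0),
                      icode = character(0), resname = character(0),
                      parent = character(0), min_distance = numeric(0)))
  }
  d2 <- cross_dist2(as.matrix(pa[, c("x", "y", "z")]),
                    as.matrix(ra[, c("x", "y", "z")]))
  dmin <- sqrt(apply(d2, 1, min))
  key <- paste(pa$chain, pa$resnum, pa$icode, sep = "\r")
  res_min <- tapply(dmin, key, min)
  u <- !duplicated(key)
  out <- data.frame(
    chain = pa$chain[u], resnum = pa$resnum[u], icode = pa$icode[u],
    resname = pa$resname[u], parent = pa$standard_parent[u],
    min_distance = as.numeric(res_min[paste(pa$chain[u], pa$resnum[u],
                                            pa$icode[u], sep = "\r")]),
    stringsAsFactors = FALSE
  )
  out <- out[out$min_distance <= cutoff & !(out$parent %in% exclude), ,
             drop = FALSE]
  out <- out[order(out$chain, out$resnum, out$icode), ]
  rownames(out) <- NULL
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Dot-sampling SASA with a deterministic golden-spiral point set,
#' Bondi-type van der Waals radii (1.70 A fallback for unknown elements)
#' and a 1.4 A water probe.
#'
#' @param s a cleaned `rnp_structure` (heavy atoms).
#' @param probe probe radius in Angstrom.
#' @param n_points sample points per atom (default 960).
#' @return list with `per_atom` (numeric vector, Angstrom^2, in atom order)
#'   and `total`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "rnp_structure"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  radii <- vdw_radius(s$atoms$element)
  per_atom <- .sasa_shrake_rupley(xyz, radii, probe, as.integer(n_points))
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Buried surface area of a protein-RNA interface
#'
#' BSA = SASA(protein alone) + SASA(RNA alone) - SASA(complex); this counts
#' the buried area of both molecules. For multi-copy complexes select the
#' chain subset defining one interface via `protein_chains`/`rna_chains`.
#'
#' @inheritParams find_contacts
#' @inheritParams compute_sasa
#' @return list of class `bsa_result` with elements `sasa_protein_alone`,
#'   `sasa_rna_alone`, `sasa_complex` and `bsa` (all Angstrom^2).
#' @export
compute_bsa <- function(s, protein_chains = NULL, rna_chains = NULL,
                        probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "rnp_structure"))
  protein_chains <- select_entity_chains(s, protein_chains, "protein")
  rna_chains <- select_entity_chains(s, rna_chains, "rna")
  prot <- subset_chains(s, protein_chains)
  rna <- subset_chains(s, rna_chains)
  both <- subset_chains(s, c(protein_chains, rna_chains))
  sp <- compute_sasa(prot, probe, n_points)$total
  sr <- compute_sasa(rna, probe, n_points)$total
  sc <- compute_sasa(both, probe, n_points)$total
  structure(list(sasa_protein_alone = sp, sasa_rna_alone = sr,
                 sasa_complex = sc, bsa = sp + sr - sc),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf(paste0("BSA: %.1f A^2  (protein alone %.1f + RNA alone %.1f",
                     " - complex %.1f)\n"),
              x$bsa, x$sasa_protein_alone, x$sasa_rna_alone,
              x$sasa_complex))
  invisible(x)
}

#' Interface frequency statistics over a set of complexes
#'
#' Per-complex counts of the 20 amino acids and 4 nucleotides in the
#' contact interface (a residue is in the interface if it has at least one
#' contact), contact partitioning between RNA backbone (phosphate + sugar)
#' and nucleobase moieties, per-base amino-acid contact fractions, and
#' aggregate means with 20th/80th percentiles (linear interpolation
#' between order statistics).
#'
#' @param tables non-empty list of `contact_table` objects, one per
#'   complex/interface.
#' @return list of class `frequency_report`; see Details.
#' @details Elements: `aa_counts` (complexes x 20 matrix), `nt_counts`
#'   (complexes x 4), `aa_mean`, `aa_q20`, `aa_q80`, `nt_mean`, `nt_q20`,
#'   `nt_q80`, `moiety_fractions` (complexes x 3, rows sum to 1),
#'   `backbone_fraction` (per complex, phosphate + sugar), and
#'   `aa_by_base` (4 x 20 matrix of contact fractions, rows sum to 1).
#' @export
frequency_report <- function(tables) {
  if (!is.list(tables) || length(tables) == 0 ||
      inherits(tables, "contact_table")) {
    if (inherits(tables, "contact_table")) tables <- list(tables)
    else stop("need a non-empty list of contact tables")
  }
  n <- length(tables)
  aa_counts <- matrix(0L, n, 20, dimnames = list(NULL, AMINO_ACIDS_3))
  nt_counts <- matrix(0L, n, 4, dimnames = list(NULL, RNA_BASES))
  moieties <- c("phosphate", "sugar", "base")
  moiety_fractions <- matrix(NA_real_, n, 3, dimnames = list(NULL, moieties))
  aa_by_base_counts <- matrix(0, 4, 20,
                              dimnames = list(RNA_BASES, AMINO_ACIDS_3))
  for (i in seq_len(n)) {
    ct <- tables[[i]]
    stopifnot(inherits(ct, "contact_table"))
    if (nrow(ct) == 0) {
      moiety_fractions[i, ] <- NA_real_
      next
    }
    pres <- unique(ct[, c("protein_chain", "protein_resnum",
                          "protein_icode", "protein_parent")])
    tab <- table(factor(pres$protein_parent, levels = AMINO_ACIDS_3))
    aa_counts[i, ] <- as.integer(tab)
    rres <- unique(ct[, c("rna_chain", "rna_resnum", "rna_icode",
                          "rna_parent")])
    tab <- table(factor(rres$rna_parent, levels = RNA_BASES))
    nt_counts[i, ] <- as.integer(tab)
    mt <- table(factor(ct$rna_moiety, levels = moieties))
    moiety_fractions[i, ] <- as.numeric(mt) / nrow(ct)
    base_ct <- ct[ct$rna_parent %in% RNA_BASES &
                    ct$protein_parent %in% AMINO_ACIDS_3, ]
    if (nrow(base_ct) > 0) {
      aa_by_base_counts <- aa_by_base_counts +
        table(factor(base_ct$rna_parent, levels = RNA_BASES),
              factor(base_ct$protein_parent, levels = AMINO_ACIDS_3))
    }
  }
  q <- function(m, p) apply(m, 2, quantile, probs = p, type = 7, names = FALSE)
  row_tot <- rowSums(aa_by_base_counts)
  aa_by_base <- sweep(aa_by_base_counts, 1, pmax(row_tot, 1), "/")
  structure(list(
    aa_counts = aa_counts, nt_counts = nt_counts,
    aa_mean = colMeans(aa_counts), aa_q20 = q(aa_counts, 0.2),
    aa_q80 = q(aa_counts, 0.8),
    nt_mean = colMeans(nt_counts), nt_q20 = q(nt_counts, 0.2),
    nt_q80 = q(nt_counts, 0.8),
    moiety_fractions = moiety_fractions,
    backbone_fraction = moiety_fractions[, "phosphate"] +
      moiety_fractions[, "sugar"],
    aa_by_base = as.matrix(aa_by_base)
  ), class = "frequency_report")
}

#' Write a contact table as TSV
#'
#' @param ct a `contact_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(ct, path) {
  stopifnot(inherits(ct, "contact_table"))
  write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
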