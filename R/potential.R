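# Distance-dependent knowledge-based protein-RNA potential with a
# decoy-derived reference state. Structures are coarse-grained to
# interaction centers (protein: backbone CA + side-chain centroid; RNA:
# phosphate P, sugar C1', base centroid). Pair frequencies observed in
# native complexes are contrasted with frequencies in randomly re-posed
# ("decoy") complexes, giving binned log-odds energies
# E = -ln((f_obs + alpha) / (f_ref + alpha)).

PROTEIN_CENTER_CLASSES <- c("backbone", "sidechain")
RNA_CENTER_CLASSES <- c("phosphate", "sugar", "base")

#' Coarse-grained interaction centers of a complex
#'
#' Protein residues contribute a backbone center (the CA position) and a
#' side-chain center (centroid of side-chain heavy atoms; the CB position
#' for alanine; none for glycine). RNA nucleotides contribute a phosphate
#' center (P), a sugar center (C1') and a base center (centroid of base
#' heavy atoms). Residues lacking the defining atoms are skipped with a
#' warning.
#'
#' @param s a cleaned `rnp_structure`.
#' @param protein_chains,rna_chains chain selections (default: all chains
#'   of the entity).
#' @return list with data.frames `protein` and `rna`; columns `chain`,
#'   `resnum`, `icode`, `restype` (canonical code), `class`, `x`, `y`, `z`.
#' @export
interaction_centers <- function(s, protein_chains = NULL, rna_chains = NULL) {
  stopifnot(inherits(s, "rnp_structure"))
  protein_chains <- select_entity_chains(s, protein_chains, "protein")
  rna_chains <- select_entity_chains(s, rna_chains, "rna")

  pa <- s$atoms[s$atoms$chain %in% protein_chains &
                  s$atoms$kind == "amino_acid" &
                  s$atoms$standard_parent != "", , drop = FALSE]
  ra <- s$atoms[s$atoms$chain %in% rna_chains &
                  s$atoms$kind == "nucleotide" &
                  s$atoms$standard_parent != "", , drop = FALSE]

  skipped <- 0L
  prot <- list()
  if (nrow(pa) > 0) {
    for (grp in split(pa, paste(pa$chain, pa$resnum, pa$icode, sep = "\r"))) {
      ca <- grp[grp$elety == "CA", , drop = FALSE]
      restype <- grp$standard_parent[1]
      if (nrow(ca) == 1) {
        prot[[length(prot) + 1]] <- data.frame(
          chain = grp$chain[1], resnum = grp$resnum[1], icode = grp$icode[1],
          restype = restype, class = "backbone",
          x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
      } else skipped <- skipped + 1L
      sc <- grp[!(grp$elety %in% PROTEIN_BACKBONE_ATOMS), , drop = FALSE]
      if (nrow(sc) > 0) {
        prot[[length(prot) + 1]] <- data.frame(
          chain = grp$chain[1], resnum = grp$resnum[1], icode = grp$icode[1],
          restype = restype, class = "sidechain",
          x = mean(sc$x), y = mean(sc$y), z = mean(sc$z),
          stringsAsFactors = FALSE)
      }
    }
  }
  rna <- list()
  if (nrow(ra) > 0) {
    for (grp in split(ra, paste(ra$chain, ra$resnum, ra$icode, sep = "\r"))) {
      restype <- grp$standard_parent[1]
      add <- function(cls, df) {
        rna[[length(rna) + 1]] <<- data.frame(
          chain = grp$chain[1], resnum = grp$resnum[1], icode = grp$icode[1],
          restype = restype, class = cls,
          x = df$x, y = df$y, z = df$z, stringsAsFactors = FALSE)
      }
      p <- grp[grp$elety == "P", , drop = FALSE]
      if (nrow(p) == 1) add("phosphate", p)
      c1 <- grp[grp$elety %in% c("C1'", "C1*"), , drop = FALSE]
      if (nrow(c1) == 1) add("sugar", c1)
      base <- grp[rna_moiety(grp$elety) == "base", , drop = FALSE]
      if (nrow(base) >= 1) {
        add("base", data.frame(x = mean(base$x), y = mean(base$y),
                               z = mean(base$z)))
      } else skipped <- skipped + 1L
    }
  }
  if (skipped > 0) {
    warning(skipped, " residue(s) lacked defining atoms for an ",
            "interaction center and were skipped")
  }
  list(protein = rbind_or_empty(prot, protein_center_proto()),
       rna = rbind_or_empty(rna, protein_center_proto()))
}

#' @keywords internal
protein_center_proto <- function() {
  data.frame(chain = character(0), resnum = integer(0), icode = character(0),
             restype = character(0), class = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             stringsAsFactors = FALSE)
}

#' @keywords internal
rbind_or_empty <- function(lst, proto) {
  if (length(lst) == 0) proto else do.call(rbind, lst)
}

#' Generate rigid-body decoy poses of a complex
#'
#' Each decoy re-poses the RNA relative to the protein: a rotation drawn
#' uniformly from SO(3) (quaternion method) about the RNA centroid,
#' followed by a translation whose direction is uniform on the sphere and
#' whose magnitude is resampled until the minimal protein-RNA heavy-atom
#' distance lies in `contact_range`, keeping the decoys in contact but out
#' of the native pose. Deterministic given `seed`.
#'
#' @param s a cleaned `rnp_structure`.
#' @param n number of decoys (`n = 0` gives an empty list).
#' @param seed integer seed.
#' @param contact_range admissible range of the minimal inter-entity
#'   heavy-atom distance (Angstrom).
#' @param max_reject rejection budget per decoy before giving up.
#' @return list of `rnp_structure` decoys; each carries a
#'   `rigid_transform` attribute (`R`, `pivot`, `shift`) describing its
#'   RNA transformation.
#' @export
generate_decoys <- function(s, n = 100, seed = 1, contact_range = c(3, 10),
                            max_reject = 1000) {
  stopifnot(inherits(s, "rnp_structure"))
  if (n == 0) return(list())
  rna_chains <- names(s$entities)[s$entities == "rna"]
  prot_chains <- names(s$entities)[s$entities == "protein"]
  if (length(rna_chains) == 0 || length(prot_chains) == 0) {
    stop("decoy generation needs both a protein and an RNA entity")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)

  is_rna <- s$atoms$chain %in% rna_chains
  rna_xyz <- as.matrix(s$atoms[is_rna, c("x", "y", "z")])
  prot_xyz <- as.matrix(s$atoms[s$atoms$chain %in% prot_chains,
                                c("x", "y", "z")])
  pivot <- colMeans(rna_xyz)
  span <- max(sqrt(rowSums(sweep(rbind(rna_xyz, prot_xyz), 2, pivot)^2)))

  decoys <- vector("list", n)
  for (k in seq_len(n)) {
    R <- random_rotation()
    rot <- sweep(sweep(rna_xyz, 2, pivot) %*% t(R), 2, pivot, "+")
    placed <- FALSE
    for (try in seq_len(max_reject)) {
      u <- random_direction()
      mag <- runif(1, 0, 2 * span)
      moved <- sweep(rot, 2, mag * u, "+")
      dmin <- min_cross_distance(prot_xyz, moved)
      if (dmin >= contact_range[1] && dmin <= contact_range[2]) {
        d <- s
        d$atoms[is_rna, c("x", "y", "z")] <- moved
        d$models <- NULL
        d$id <- sprintf("%s_decoy%03d", s$id, k)
        attr(d, "rigid_transform") <- list(R = R, pivot = pivot,
                                           shift = mag * u)
        decoys[[k]] <- d
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("decoy placement failed after ", max_reject, " rejections; ",
           "consider a different contact_range or geometry")
    }
  }
  decoys
}

#' @keywords internal
empty_energy_array <- function(n_bins) {
  array(0, dim = c(20, 2, 4, 3, n_bins),
        dimnames = list(AMINO_ACIDS_3, PROTEIN_CENTER_CLASSES,
                        RNA_BASES, RNA_CENTER_CLASSES, NULL))
}

# tally center pairs below r_max into the 5-d count array
#' @keywords internal
count_pairs <- function(cp, cr, bin_width, r_max, counts) {
  if (nrow(cp) == 0 || nrow(cr) == 0) return(counts)
  d2 <- cross_dist2(as.matrix(cp[, c("x", "y", "z")]),
                    as.matrix(cr[, c("x", "y", "z")]))
  hit <- which(d2 < r_max^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(counts)
  i <- hit[, 1]; j <- hit[, 2]
  bin <- pmin(floor(sqrt(d2[hit]) / bin_width) + 1L,
              as.integer(round(r_max / bin_width)))
  ai <- match(cp$restype[i], AMINO_ACIDS_3)
  pi <- match(cp$class[i], PROTEIN_CENTER_CLASSES)
  ni <- match(cr$restype[j], RNA_BASES)
  ri <- match(cr$class[j], RNA_CENTER_CLASSES)
  ok <- !is.na(ai) & !is.na(ni)
  idx <- ai[ok] + 20L * ((pi[ok] - 1L) + 2L * ((ni[ok] - 1L) +
           4L * ((ri[ok] - 1L) + 3L * (bin[ok] - 1L))))
  tab <- tabulate(idx, nbins = length(counts))
  counts + array(tab, dim = dim(counts), dimnames = dimnames(counts))
}

#' Train the decoy-referenced potential
#'
#' Counts interaction-center pairs per type and distance bin in the native
#' complexes (`f_obs`) and in rigid-body decoys of the same complexes
#' (`f_ref`, normalised to the native total), then sets
#' `E = -ln((f_obs + alpha) / (f_ref + alpha))`. A (type, bin) cell
#' observed in neither native nor decoy sets keeps `E = 0`.
#'
#' @param structures non-empty list of cleaned `rnp_structure` complexes.
#' @param n_decoys decoys per complex.
#' @param seed integer seed controlling decoy generation.
#' @param alpha Laplace pseudocount.
#' @param bin_width distance bin width (Angstrom).
#' @param r_max maximal pair distance (Angstrom); 0.5 and 7.0 give 14 bins.
#' @return object of class `rnp_potential`: list with `bin_width`, `r_max`,
#'   `n_bins`, `alpha`, `energies` (5-d array amino acid x protein class x
#'   base x RNA class x bin) and `training_meta`.
#' @export
train_potential <- function(structures, n_decoys = 100, seed = 1,
                            alpha = 1.0, bin_width = 0.5, r_max = 7.0) {
  if (!is.list(structures) || length(structures) == 0) {
    stop("need a non-empty list of structures")
  }
  n_bins <- as.integer(round(r_max / bin_width))
  f_obs <- empty_energy_array(n_bins)
  f_ref <- empty_energy_array(n_bins)

  for (si in seq_along(structures)) {
    s <- structures[[si]]
    cen <- interaction_centers(s)
    f_obs <- count_pairs(cen$protein, cen$rna, bin_width, r_max, f_obs)
    decoys <- generate_decoys(s, n = n_decoys, seed = seed + si)
    for (d in decoys) {
      tr <- attr(d, "rigid_transform")
      cr <- transform_centers(cen$rna, tr)
      f_ref <- count_pairs(cen$protein, cr, bin_width, r_max, f_ref)
    }
  }
  total_obs <- sum(f_obs)
  total_ref <- sum(f_ref)
  if (total_obs == 0) stop("no native center pairs below r_max")
  scale <- if (total_ref > 0) total_obs / total_ref else 0
  energies <- -log((f_obs + alpha) / (f_ref * scale + alpha))

  structure(list(
    bin_width = bin_width, r_max = r_max, n_bins = n_bins, alpha = alpha,
    energies = energies,
    training_meta = list(
      structures = vapply(structures, function(s) s$id, character(1)),
      n_decoys = n_decoys, seed = seed,
      total_native_pairs = total_obs, total_decoy_pairs = total_ref)
  ), class = "rnp_potential")
}

#' @keywords internal
transform_centers <- function(cr, tr) {
  if (nrow(cr) == 0) return(cr)
  xyz <- as.matrix(cr[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, tr$pivot) %*% t(tr$R), 2, tr$pivot + tr$shift,
               "+")
  cr[, c("x", "y", "z")] <- xyz
  cr
}

# sum of pair energies between two center sets; returns dars and n_pairs
#' @keywords internal
score_centers <- function(cp, cr, m) {
  if (nrow(cp) == 0 || nrow(cr) == 0) return(list(dars = 0, n_pairs = 0L))
  d2 <- cross_dist2(as.matrix(cp[, c("x", "y", "z")]),
                    as.matrix(cr[, c("x", "y", "z")]))
  hit <- which(d2 < m$r_max^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(list(dars = 0, n_pairs = 0L))
  i <- hit[, 1]; j <- hit[, 2]
  bin <- pmin(floor(sqrt(d2[hit]) / m$bin_width) + 1L, m$n_bins)
  ai <- match(cp$restype[i], AMINO_ACIDS_3)
  pi <- match(cp$class[i], PROTEIN_CENTER_CLASSES)
  ni <- match(cr$restype[j], RNA_BASES)
  ri <- match(cr$class[j], RNA_CENTER_CLASSES)
  ok <- !is.na(ai) & !is.na(ni)
  idx <- ai[ok] + 20L * ((pi[ok] - 1L) + 2L * ((ni[ok] - 1L) +
           4L * ((ri[ok] - 1L) + 3L * (bin[ok] - 1L))))
  list(dars = sum(m$energies[idx]), n_pairs = sum(ok))
}

#' Score a protein-RNA complex with a trained potential
#'
#' Sums the binned pair energies over all (protein center, RNA center)
#' pairs closer than the potential's `r_max` between the selected chain
#' sets. Lower (more negative) scores indicate more native-like packing.
#'
#' @param s a cleaned `rnp_structure`.
#' @param m an `rnp_potential` from [train_potential()].
#' @param protein_chains,rna_chains chain selections.
#' @return list of class `complex_score` with `dars` (dimensionless score)
#'   and `n_pairs`.
#' @export
score_complex <- function(s, m, protein_chains = NULL, rna_chains = NULL) {
  stopifnot(inherits(s, "rnp_structure"), inherits(m, "rnp_potential"))
  cen <- interaction_centers(s, protein_chains, rna_chains)
  if (nrow(cen$protein) == 0 || nrow(cen$rna) == 0) {
    stop("empty chain selection: no interaction centers")
  }
  sc <- score_centers(cen$protein, cen$rna, m)
  structure(sc, class = "complex_score")
}

#' @export
print.complex_score <- function(x, ...) {
  cat(sprintf("complex score: %.4f over %d center pairs\n",
              x$dars, x$n_pairs))
  invisible(x)
}

#' Save a potential model as JSON
#'
#' Versioned schema containing bin layout, pair types, flattened energy
#' table and training metadata.
#'
#' @param m an `rnp_potential`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_potential <- function(m, path) {
  stopifnot(inherits(m, "rnp_potential"))
  obj <- list(
    schema = "rnp_potential/1",
    bin_width = m$bin_width, r_max = m$r_max, n_bins = m$n_bins,
    alpha = m$alpha,
    dims = dim(m$energies),
    dimnames = dimnames(m$energies)[1:4],
    energies = as.numeric(m$energies),
    training_meta = m$training_meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a potential model from JSON
#'
#' @param path path to a JSON file written by [write_potential()].
#' @return an `rnp_potential`.
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "rnp_potential/1")) {
    stop("unrecognised potential schema: ", obj$schema)
  }
  energies <- array(obj$energies, dim = obj$dims)
  dimnames(energies) <- c(lapply(obj$dimnames, as.character), list(NULL))
  structure(list(bin_width = obj$bin_width, r_max = obj$r_max,
                 n_bins = obj$n_bins, alpha = obj$alpha,
                 energies = energies, training_meta = obj$training_meta),
            class = "rnp_potential")
}

#' Default pre-trained potential
#'
#' A small potential trained on the package's own synthetic fixture cohort
#' (16 seeded complexes with rotated sequences and a spread of planted
#' contact distances, 40 decoys each), built deterministically on first
#' use and cached for the session. Suitable for examples, tests and
#' offline scanning; retrain on real complexes with [train_potential()]
#' for production use.
#'
#' @return an `rnp_potential`.
#' @export
default_model <- function() {
  if (is.null(.alascan_cache$default_model)) {
    .alascan_cache$default_model <-
      train_potential(default_training_cohort(), n_decoys = 40,
                      seed = 424242)
  }
  .alascan_cache$default_model
}

# training cohort behind default_model(): sequences rotated so that every
# base occurs at the planted target positions, planted distances spread
# over ~0.5 A so neighbouring distance bins are populated
#' @keywords internal
default_training_cohort <- function(n = 16, seed_base = 101) {
  base_seq <- "GACGUCGUAC"
  lapply(seq_len(n), function(i) {
    rot <- (i - 1) %% nchar(base_seq)
    seq_i <- paste0(substr(base_seq, rot + 1, nchar(base_seq)),
                    substr(base_seq, 1, rot))
    off <- 0.15 * ((i - 1) %% 4)
    planted <- lapply(default_planted_contacts(), function(pc) {
      pc$dist <- pc$dist + off
      pc
    })
    make_complex(fixture_spec(rna_sequence = seq_i,
                              planted_contacts = planted,
                              seed = seed_base + i - 1))
  })
}
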