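# Seeded generator of synthetic protein-RNA complexes. The RNA is built on
# an idealised A-form-like helical lattice (twist 32.7 degrees, rise 2.81 A
# per base pair) with phosphate, sugar and base heavy-atom positions that
# satisfy the package's own Watson-Crick pair detector by construction.
# The protein is a reduced model (backbone N/CA/C/O + CB + one distal
# side-chain atom) whose side chains are planted at user-specified
# distances from chosen RNA moieties, so that trained potentials reward
# native-like contacts. Everything is a pure function of the FixtureSpec
# (seed included).

HELIX_TWIST_DEG <- 32.7
HELIX_RISE <- 2.81

# Template nucleotide geometry, strand-1 local frame, base plane z = 0.
# The Watson-Crick face atom sits at (1.45, 0, 0); the partner strand is
# generated by a 180 degree rotation about y, which places the two WC
# atoms 2.9 A apart and the two C1' atoms 10.4 A apart.
#' @keywords internal
nucleotide_template <- function(base) {
  stopifnot(base %in% RNA_BASES)
  sugar_phos <- rbind(
    "C1'" = c(5.2, -1.0, 0.0),
    "O4'" = c(5.9,  0.2, 0.3),
    "C2'" = c(6.4, -1.8, 0.2),
    "O2'" = c(6.8, -3.1, 0.5),
    "C3'" = c(7.5, -1.4, 0.8),
    "O3'" = c(8.4, -2.0, 1.8),
    "C4'" = c(7.3, -0.2, 0.6),
    "C5'" = c(8.0,  1.0, 1.1),
    "O5'" = c(8.3,  1.9, 2.1),
    "P"   = c(8.7,  2.6, 3.3),
    "OP1" = c(10.1, 2.9, 3.5),
    "OP2" = c(8.1,  3.8, 4.0)
  )
  if (base %in% c("A", "G")) {
    ring <- rbind(
      "N1" = c(1.450,  0.000, 0),
      "C2" = c(2.145, -1.204, 0),
      "N3" = c(3.535, -1.204, 0),
      "C4" = c(4.230,  0.000, 0),
      "C5" = c(3.535,  1.204, 0),
      "C6" = c(2.145,  1.204, 0),
      "N7" = c(4.200,  2.300, 0),
      "C8" = c(5.500,  2.000, 0),
      "N9" = c(5.500,  0.600, 0)
    )
    exo <- rbind(c(1.535, 2.261, 0))
    rownames(exo) <- if (base == "A") "N6" else "O6"
  } else {
    ring <- rbind(
      "N3" = c(1.450,  0.000, 0),
      "C2" = c(2.145, -1.204, 0),
      "N1" = c(3.535, -1.204, 0),
      "C6" = c(4.230,  0.000, 0),
      "C5" = c(3.535,  1.204, 0),
      "C4" = c(2.145,  1.204, 0)
    )
    exo <- rbind("O2" = c(1.535, -2.261, 0),
                 c(1.535, 2.261, 0))
    rownames(exo)[2] <- if (base == "C") "N4" else "O4"
  }
  rbind(ring, exo, sugar_phos)
}

#' @keywords internal
complement_base <- function(b) {
  unname(c(A = "U", U = "A", G = "C", C = "G")[b])
}

#' Specification of a synthetic protein-RNA complex
#'
#' @param rna_form one of `"single_strand"`, `"duplex"`, `"hairpin"`,
#'   `"two_stem"`.
#' @param rna_sequence RNA sequence (characters from A/C/G/U). For a duplex
#'   this is strand 1 and strand 2 is its reverse complement; for a hairpin
#'   the 3'-side stem nucleotides are rebuilt as the reverse complement of
#'   the 5' side.
#' @param n_protein_residues total protein length (planted + distal
#'   residues), at least the number of planted contacts.
#' @param planted_contacts list of lists with elements `res` (3-letter
#'   amino-acid code), `moiety` (`"phosphate"`, `"sugar"` or `"base"`) and
#'   `dist` (target heavy-atom distance, >= 2.5 A).
#' @param seed integer seed; fixtures are pure functions of the spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(rna_form = "duplex",
                         rna_sequence = "GACGUCGUAC",
                         n_protein_residues = 12,
                         planted_contacts = default_planted_contacts(),
                         seed = 1) {
  rna_form <- match.arg(rna_form,
                        c("single_strand", "duplex", "hairpin", "two_stem"))
  bases <- strsplit(toupper(rna_sequence), "")[[1]]
  if (!all(bases %in% RNA_BASES)) {
    stop("invalid base in rna_sequence: ",
         paste(setdiff(bases, RNA_BASES), collapse = ","))
  }
  for (pc in planted_contacts) {
    stopifnot(pc$res %in% AMINO_ACIDS_3,
              pc$moiety %in% c("phosphate", "sugar", "base"))
    if (pc$dist < 2.5) stop("planted contact distance must be >= 2.5 A")
  }
  if (n_protein_residues < length(planted_contacts)) {
    stop("n_protein_residues smaller than the number of planted contacts")
  }
  structure(list(rna_form = rna_form, rna_sequence = bases,
                 n_protein_residues = n_protein_residues,
                 planted_contacts = planted_contacts, seed = seed),
            class = "fixture_spec")
}

#' Default planted contacts
#'
#' A native-like contact pattern: basic side chains on RNA phosphates plus
#' polar contacts to sugar and base moieties.
#' @return list usable as `planted_contacts` in [fixture_spec()].
#' @export
default_planted_contacts <- function() {
  list(
    list(res = "ARG", moiety = "phosphate", dist = 3.0),
    list(res = "LYS", moiety = "phosphate", dist = 3.1),
    list(res = "SER", moiety = "sugar",     dist = 3.3),
    list(res = "GLN", moiety = "base",      dist = 3.2),
    list(res = "TYR", moiety = "base",      dist = 3.4)
  )
}

# distal side-chain atom name used for the reduced side-chain
# representation of each residue type
#' @keywords internal
SIDECHAIN_TIP_ATOM <- c(
  ARG = "NH1", LYS = "NZ", SER = "OG", THR = "OG1", TYR = "OH",
  GLN = "NE2", ASN = "OD1", GLU = "OE1", ASP = "OD1", HIS = "NE2",
  PHE = "CZ", TRP = "NE1", LEU = "CD1", ILE = "CD1", VAL = "CG1",
  MET = "SD", CYS = "SG", ALA = "", GLY = "", PRO = "CG"
)

#' Build the RNA part of a fixture
#'
#' Generates an A-form-like single strand, duplex, hairpin or two-stem RNA
#' with heavy atoms sufficient for every pipeline operation (phosphate
#' group, sugar ring including O2'/O3'/O4'/O5', and base ring atoms
#' including the Watson-Crick face). Duplex and hairpin forms satisfy
#' [detect_base_pairs()] by construction.
#'
#' @param spec a [fixture_spec()].
#' @return an `rnp_structure` containing only RNA chains (entity typing
#'   deferred until a complex is assembled; see [make_complex()]).
#' @export
make_rna <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed %% .Machine$integer.max)

  rows <- switch(spec$rna_form,
    duplex = rna_duplex_rows(spec$rna_sequence),
    hairpin = rna_hairpin_rows(spec$rna_sequence),
    single_strand = rna_single_rows(spec$rna_sequence, chain = "R"),
    two_stem = rna_two_stem_rows(spec$rna_sequence)
  )
  # seeded sub-Angstrom jitter: distinct fixtures per seed, all geometric
  # detection windows preserved
  n <- nrow(rows)
  rows$x <- rows$x + rnorm(n, 0, 0.04)
  rows$y <- rows$y + rnorm(n, 0, 0.04)
  rows$z <- rows$z + rnorm(n, 0, 0.04)
  rna_structure_from_rows(rows, id = sprintf("fixture_rna_%d", spec$seed))
}

#' @keywords internal
nucleotide_rows <- function(base, chain, resnum, transform) {
  tmpl <- nucleotide_template(base)
  xyz <- t(apply(tmpl, 1, transform))
  data.frame(
    record = "ATOM", eleno = NA_integer_, elety = rownames(tmpl),
    altloc = "", resname = base, chain = chain, resnum = resnum,
    icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1,
    element = substr(gsub("[^A-Z]", "", rownames(tmpl)), 1, 1),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
pair_transform <- function(k, strand) {
  R <- rot_z(k * HELIX_TWIST_DEG)
  flip <- rot_y180()
  force(strand)
  function(v) {
    if (strand == 2) v <- as.numeric(flip %*% v)
    as.numeric(R %*% v) + c(0, 0, k * HELIX_RISE)
  }
}

#' @keywords internal
rna_duplex_rows <- function(bases) {
  n <- length(bases)
  comp <- rev(unname(vapply(bases, complement_base, character(1))))
  rows <- list()
  for (k in seq_len(n)) {
    rows[[k]] <- nucleotide_rows(bases[k], "B", k, pair_transform(k - 1, 1))
  }
  for (j in seq_len(n)) {
    # chain C residue j partners chain B residue n + 1 - j
    k <- n - j + 1
    rows[[n + j]] <- nucleotide_rows(comp[j], "C", j,
                                     pair_transform(k - 1, 2))
  }
  do.call(rbind, rows)
}

#' @keywords internal
rna_hairpin_rows <- function(bases, chain = "R", loop_len = 4,
                             resnum_offset = 0, post = identity) {
  n <- length(bases)
  n_stem <- (n - loop_len) %/% 2
  if (n_stem < 3) stop("hairpin fixture needs at least a 3-bp stem")
  n_used <- 2 * n_stem + loop_len
  bases <- bases[seq_len(n_used)]
  rows <- list()
  for (i in seq_len(n_stem)) {
    rows[[i]] <- nucleotide_rows(bases[i], chain, i + resnum_offset,
                                 function(v) post(pair_transform(i - 1, 1)(v)))
  }
  z_top <- (n_stem - 1) * HELIX_RISE
  for (m in seq_len(loop_len)) {
    i <- n_stem + m
    R <- rot_z((n_stem - 1) * HELIX_TWIST_DEG + m * 50)
    rows[[i]] <- nucleotide_rows(bases[i], chain, i + resnum_offset,
      function(v) post(as.numeric(R %*% (v + c(2, 0, 0))) +
                         c(0, 0, z_top + 3.0 * m)))
  }
  for (m in seq_len(n_stem)) {
    i <- n_stem + loop_len + m
    p <- n_stem - m           # 0-based pair index of the partner
    b <- complement_base(bases[n_stem - m + 1])
    rows[[i]] <- nucleotide_rows(b, chain, i + resnum_offset,
                                 function(v) post(pair_transform(p, 2)(v)))
  }
  do.call(rbind, rows)
}

#' @keywords internal
rna_single_rows <- function(bases, chain = "R") {
  rows <- lapply(seq_along(bases), function(i) {
    R <- rot_z((i - 1) * HELIX_TWIST_DEG)
    nucleotide_rows(bases[i], chain, i,
                    function(v) as.numeric(R %*% v) + c(0, 0, (i - 1) * 3.4))
  })
  do.call(rbind, rows)
}

#' @keywords internal
rna_two_stem_rows <- function(bases) {
  n <- length(bases)
  half <- n %/% 2
  b1 <- bases[seq_len(half)]
  b2 <- bases[seq(half + 1, n)]
  r1 <- rna_hairpin_rows(b1, chain = "R")
  n1 <- max(r1$resnum)
  shift <- function(v) as.numeric(rot_x(90) %*% v) + c(30, 0, 0)
  r2 <- rna_hairpin_rows(b2, chain = "R", resnum_offset = n1, post = shift)
  rbind(r1, r2)
}

#' @keywords internal
rna_structure_from_rows <- function(rows, id) {
  rows$eleno <- seq_len(nrow(rows))
  cls <- classify_resname(rows$resname)
  rows$kind <- cls$kind
  rows$standard_parent <- cls$standard_parent
  rows$is_modified <- cls$is_modified
  s <- structure(list(id = id, method = "other", resolution = NA_real_,
                      n_models = 1L, atoms = rows, models = NULL,
                      cleaned = TRUE),
                 class = "rnp_structure")
  s$entities <- chain_entities(s)
  s
}

#' Build a complete synthetic protein-RNA complex
#'
#' Assembles the RNA from [make_rna()] with a reduced-representation
#' protein chain (chain `P`) positioned so that every planted contact is
#' realised within 0.2 A of its target distance; remaining residues are
#' placed well outside the interface. The result is clash-free: the
#' minimal protein-RNA heavy-atom distance is at least 2.5 A.
#'
#' @param spec a [fixture_spec()].
#' @return a cleaned `rnp_structure` with protein chain `P` and the RNA
#'   chains of the chosen form.
#' @export
#' @examples
#' cx <- make_complex(fixture_spec(seed = 7))
#' cx$entities
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rna <- make_rna(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((spec$seed + 7919) %% .Machine$integer.max)

  rna_xyz <- as.matrix(rna$atoms[, c("x", "y", "z")])
  centroid <- colMeans(rna_xyz)

  n_planted <- length(spec$planted_contacts)
  n_total <- spec$n_protein_residues
  rows <- list()

  # targets: one nucleotide per planted contact, spaced two apart
  rna_res <- unique(rna$atoms[, c("chain", "resnum")])
  target_idx <- ((seq_len(n_planted) - 1) * 2 + 2 - 1) %% nrow(rna_res) + 1

  # principal axis of the RNA, for outward placement directions
  pc1 <- svd(sweep(rna_xyz, 2, centroid))$v[, 1]

  moiety_atom <- c(phosphate = "P", sugar = "C1'", base = "C5")
  for (i in seq_len(n_planted)) {
    pc <- spec$planted_contacts[[i]]
    tr <- rna_res[target_idx[i], ]
    ra <- rna$atoms[rna$atoms$chain == tr$chain &
                      rna$atoms$resnum == tr$resnum, ]
    a <- ra[ra$elety == moiety_atom[[pc$moiety]], c("x", "y", "z")]
    if (nrow(a) != 1) stop("infeasible planting: target atom missing")
    a <- as.numeric(a[1, ])
    rows[[i]] <- place_planted_residue(pc$res, i, a, pc$dist, rna_xyz,
                                       centroid, pc1)
  }

  # distal (non-interface) residues on a line far outside the 7 A shell
  far_pool <- c("LEU", "GLU", "VAL", "THR", "ASP", "GLY", "PRO", "ILE",
                "PHE", "ASN", "MET", "HIS")
  r_max <- max(sqrt(rowSums(sweep(rna_xyz, 2, centroid)^2)))
  base_pos <- centroid + c(r_max + 16, 0, -0.5 * r_max)
  for (j in seq_len(n_total - n_planted)) {
    res <- far_pool[(j - 1) %% length(far_pool) + 1]
    ca <- base_pos + c(0, 0, 3.8 * (j - 1))
    fr <- far_residue_rows(res, n_planted + j, ca)
    fr$planted <- FALSE
    rows[[n_planted + j]] <- fr
  }

  prot <- do.call(rbind, rows)
  n <- nrow(prot)
  # jitter everything except planted tip atoms, so target distances stay
  # exact while fixtures differ per seed
  fixed <- prot$planted
  prot$planted <- NULL
  prot$x <- prot$x + ifelse(fixed, 0, rnorm(n, 0, 0.03))
  prot$y <- prot$y + ifelse(fixed, 0, rnorm(n, 0, 0.03))
  prot$z <- prot$z + ifelse(fixed, 0, rnorm(n, 0, 0.03))

  all_rows <- rbind(prot, rna$atoms[, names(prot)])
  s <- rna_structure_from_rows(all_rows,
                               id = sprintf("fixture_complex_%d", spec$seed))
  s$method <- "xray"
  s$resolution <- 2.0

  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  if (min_cross_distance(prot_xyz, rna_xyz) < 2.5 - 1e-9) {
    stop("infeasible planting: protein-RNA clash below 2.5 A")
  }
  s
}

# residue whose side-chain tip atom sits at distance d from target atom a,
# growing outward along unit vector u
#' @keywords internal
planted_residue_rows <- function(res, resnum, a, u, d) {
  b <- orthobasis(u)
  tip <- a + d * u
  has_tip <- SIDECHAIN_TIP_ATOM[[res]] != ""
  cb <- tip + 1.5 * u + 0.3 * b$p1
  if (!has_tip) cb <- a + d * u     # ALA/GLY: CB itself is the planted atom
  ca <- cb + 1.53 * u - 0.4 * b$p1
  nn <- ca + 1.45 * b$p1 + 0.4 * u
  cc <- ca + 1.52 * b$p2 + 0.4 * u
  oo <- cc + 1.23 * u
  coords <- rbind(N = nn, CA = ca, C = cc, O = oo, CB = cb)
  planted <- rep(FALSE, nrow(coords))
  if (has_tip && res != "GLY") {
    coords <- rbind(coords, setNames_row(tip, SIDECHAIN_TIP_ATOM[[res]]))
    planted <- c(planted, TRUE)
  }
  if (res == "GLY") {
    keep <- rownames(coords) != "CB"
    coords <- coords[keep, , drop = FALSE]
    planted <- planted[keep]
  }
  if (!has_tip && res == "ALA") planted[rownames(coords) == "CB"] <- TRUE
  out <- residue_rows_from_coords(res, resnum, coords)
  out$planted <- planted
  out
}

# choose, deterministically, an outward direction for a planted residue
# that keeps every non-tip atom at least 2.7 A from all RNA atoms
#' @keywords internal
place_planted_residue <- function(res, resnum, a, d, rna_xyz, centroid,
                                  axis) {
  target_row <- which.min(rowSums(sweep(rna_xyz, 2, a)^2))
  w <- a - centroid
  radial <- w - sum(w * axis) * axis
  if (sqrt(sum(radial^2)) < 1e-6) radial <- orthobasis(axis)$p1
  u0 <- unit(radial)
  tang <- unit(pracma_cross(axis, u0))
  best <- NULL
  best_clear <- -Inf
  az_grid <- c(0, as.vector(rbind(seq(15, 180, 15), -seq(15, 180, 15))))
  el_grid <- c(0, as.vector(rbind(seq(15, 60, 15), -seq(15, 60, 15))))
  for (az in az_grid * pi / 180) {
    for (el in el_grid * pi / 180) {
      u <- unit(cos(el) * (cos(az) * u0 + sin(az) * tang) +
                  sin(el) * axis)
      cand <- planted_residue_rows(res, resnum, a, u, d)
      xyz <- as.matrix(cand[, c("x", "y", "z")])
      d2 <- cross_dist2(xyz, rna_xyz)
      # the engineered tip-target distance itself does not count as a clash
      d2[cand$planted, target_row] <- Inf
      clear <- sqrt(min(d2))
      if (clear > best_clear) {
        best <- cand
        best_clear <- clear
      }
      if (clear >= 2.7) return(cand)
    }
  }
  if (best_clear < 2.5) {
    stop("infeasible planting: residue ", res, " at ", d,
         " A cannot be placed without clashes")
  }
  best
}

#' @keywords internal
far_residue_rows <- function(res, resnum, ca) {
  coords <- rbind(
    N = ca + c(-1.2, 0.8, 0), CA = ca, C = ca + c(1.3, 0.7, 0),
    O = ca + c(1.6, 1.9, 0)
  )
  if (res != "GLY") {
    cb <- ca + c(0.4, -1.4, 0.6)
    coords <- rbind(coords, CB = cb)
    tip <- SIDECHAIN_TIP_ATOM[[res]]
    if (tip != "") {
      coords <- rbind(coords, setNames_row(cb + c(0.5, -1.2, 0.8), tip))
    }
  }
  residue_rows_from_coords(res, resnum, coords)
}

#' @keywords internal
setNames_row <- function(v, nm) {
  m <- matrix(v, 1, 3)
  rownames(m) <- nm
  m
}

#' @keywords internal
residue_rows_from_coords <- function(res, resnum, coords) {
  data.frame(
    record = "ATOM", eleno = NA_integer_, elety = rownames(coords),
    altloc = "", resname = res, chain = "P", resnum = resnum, icode = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], occupancy = 1,
    element = substr(gsub("[^A-Z]", "", rownames(coords)), 1, 1),
    stringsAsFactors = FALSE
  )
}

# save/restore the global RNG state so generators are pure functions of
# their spec without disturbing the caller's random stream
#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cohort of seeded fixture complexes
#'
#' Convenience wrapper producing `n` complexes with consecutive seeds,
#' used for potential training and for property-style tests.
#'
#' @param n number of complexes.
#' @param seed_base first seed; complex `i` uses seed `seed_base + i - 1`.
#' @param ... passed to [fixture_spec()].
#' @return list of `rnp_structure` objects.
#' @export
fixture_cohort <- function(n = 12, seed_base = 101, ...) {
  lapply(seq_len(n), function(i) {
    make_complex(fixture_spec(seed = seed_base + i - 1, ...))
  })
}
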