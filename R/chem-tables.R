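# Chemical dictionaries shared across modules: residue classification,
# modified-residue parent mapping, atom moiety tables and van der Waals radii.

#' @keywords internal
AMINO_ACIDS_3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' @keywords internal
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' @keywords internal
RNA_BASES <- c("A", "C", "G", "U")

# Residue names that count as RNA nucleotides directly (PDB v3 one-letter
# ribonucleotide codes plus a few legacy spellings).
#' @keywords internal
RNA_RESNAMES <- c("A", "C", "G", "U", "ADE", "CYT", "GUA", "URA", "URI")

# Modified polymer residues mapped to their canonical parent. Nucleotide
# entries cover the common post-transcriptional modifications seen in
# structures of tRNA, rRNA and snRNA complexes; amino-acid entries cover
# frequent crystallographic substitutions and phosphorylations.
#' @keywords internal
MODIFIED_RESIDUE_PARENT <- c(
  # nucleotides
  PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  DHU = "U", "2MU" = "U", "70U" = "U", "5BU" = "U", RT  = "U",
  "1MA" = "A", "2MA" = "A", MIA = "A", "6MA" = "A", A2M = "A", MA6 = "A",
  RIA = "A", T6A = "A", AVC = "A",
  "5MC" = "C", OMC = "C", "4OC" = "C", CCC = "C", M5C = "C", CBV = "C",
  "1MG" = "G", "2MG" = "G", "7MG" = "G", M2G = "G", OMG = "G", YG  = "G",
  G7M = "G", QUO = "G", GTP = "G", GDP = "G",
  # amino acids
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  CME = "CYS", CSD = "CYS", OCS = "CYS", MLY = "LYS", KCX = "LYS",
  LLP = "LYS", HYP = "PRO", PCA = "GLU", CGU = "GLU", FME = "MET",
  CSX = "CYS", SMC = "CYS", ALY = "LYS", M3L = "LYS", DHA = "SER"
)

#' @keywords internal
WATER_RESNAMES <- c("HOH", "DOD", "WAT", "H2O")

# Protein backbone heavy atoms; everything else on an amino acid is side chain.
#' @keywords internal
PROTEIN_BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# RNA moiety partition. O5'/O3' are assigned to the sugar so that
# "backbone" = phosphate + sugar gives the conventional phosphate group
# {P, OP1, OP2, OP3}. Both prime and legacy star spellings are accepted.
#' @keywords internal
RNA_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")

#' @keywords internal
RNA_SUGAR_ATOMS <- c(
  "C1'", "C2'", "C3'", "C4'", "C5'", "O2'", "O3'", "O4'", "O5'",
  "C1*", "C2*", "C3*", "C4*", "C5*", "O2*", "O3*", "O4*", "O5*"
)

# Bondi-type van der Waals radii (Angstrom) used by the SASA sampler.
#' @keywords internal
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, SE = 1.90,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, H = 1.20,
  MG = 1.73, ZN = 1.39, MN = 1.73, FE = 1.70, K = 2.75, "NA" = 2.27
)

#' @keywords internal
VDW_DEFAULT_RADIUS <- 1.70

#' Classify a residue name
#'
#' Maps a 3-letter (or 1-letter nucleotide) residue name to its polymer kind
#' and canonical parent code, resolving common modified residues.
#'
#' @param resname character vector of residue names as found in PDB files.
#' @return data.frame with columns `kind` (`"amino_acid"`, `"nucleotide"` or
#'   `"other"`), `standard_parent` (canonical code or `""`) and `is_modified`.
#' @keywords internal
classify_resname <- function(resname) {
  resname <- toupper(trimws(resname))
  kind <- rep("other", length(resname))
  parent <- rep("", length(resname))
  modified <- rep(FALSE, length(resname))

  is_aa <- resname %in% AMINO_ACIDS_3
  kind[is_aa] <- "amino_acid"
  parent[is_aa] <- resname[is_aa]

  is_nt <- resname %in% RNA_RESNAMES
  kind[is_nt] <- "nucleotide"
  parent[is_nt] <- substr(resname[is_nt], 1, 1)
  parent[is_nt & resname == "URI"] <- "U"

  is_mod <- resname %in% names(MODIFIED_RESIDUE_PARENT)
  mod_parent <- MODIFIED_RESIDUE_PARENT[resname[is_mod]]
  kind[is_mod] <- ifelse(mod_parent %in% RNA_BASES, "nucleotide", "amino_acid")
  parent[is_mod] <- mod_parent
  modified[is_mod] <- TRUE

  data.frame(kind = kind, standard_parent = unname(parent),
             is_modified = modified, stringsAsFactors = FALSE)
}

#' Moiety of a protein heavy atom
#' @keywords internal
protein_moiety <- function(atom_name) {
  ifelse(toupper(trimws(atom_name)) %in% PROTEIN_BACKBONE_ATOMS,
         "backbone", "sidechain")
}

#' Moiety of an RNA heavy atom
#' @keywords internal
rna_moiety <- function(atom_name) {
  a <- toupper(trimws(atom_name))
  out <- rep("base", length(a))
  out[a %in% RNA_SUGAR_ATOMS] <- "sugar"
  out[a %in% RNA_PHOSPHATE_ATOMS] <- "phosphate"
  out
}

#' Van der Waals radius per element
#' @keywords internal
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(trimws(element))]
  r[is.na(r)] <- VDW_DEFAULT_RADIUS
  unname(r)
}
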