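# Shared test helpers: hand-written PDB snippets and cached model/fixtures.

# cached default model (training takes a few seconds; share across tests)
test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_model()
    m
  }
})

pdb_atom_line <- function(serial, name, resname, chain, resnum, x, y, z,
                          altloc = " ", occ = 1.0, element = NULL,
                          record = "ATOM  ", icode = " ") {
  if (is.null(element)) element <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resname, chain, resnum, icode,
          x, y, z, occ, 0, element)
}

write_test_pdb <- function(lines, header = character(0)) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(header, lines, "END"), f)
  f
}

# a minimal parseable complex: 3 amino acids + 3 nucleotides with enough
# atoms for chain typing (not for geometry work; use fixtures for that)
tiny_complex_pdb <- function() {
  l <- c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "N", "LEU", "A", 2, 3, 0, 0),
    pdb_atom_line(4, "CA", "LEU", "A", 2, 4.5, 0, 0),
    pdb_atom_line(5, "N", "SER", "A", 3, 6, 0, 0),
    pdb_atom_line(6, "CA", "SER", "A", 3, 7.5, 0, 0),
    pdb_atom_line(7, "P", "A", "B", 1, 0, 8, 0),
    pdb_atom_line(8, "C1'", "A", "B", 1, 1, 8, 0),
    pdb_atom_line(9, "P", "G", "B", 2, 2, 8, 0),
    pdb_atom_line(10, "C1'", "G", "B", 2, 3, 8, 0),
    pdb_atom_line(11, "P", "U", "B", 3, 4, 8, 0),
    pdb_atom_line(12, "C1'", "U", "B", 3, 5, 8, 0)
  )
  write_test_pdb(l)
}

# build an rnp_structure straight from atom rows (internal constructor)
structure_from_rows <- function(df, id = "test") {
  AlaScanRNP:::rna_structure_from_rows(df, id)
}

atom_row <- function(elety, resname, chain, resnum, x, y, z,
                     element = NULL) {
  if (is.null(element)) element <- substr(gsub("[^A-Z]", "", elety), 1, 1)
  data.frame(record = "ATOM", eleno = NA_integer_, elety = elety,
             altloc = "", resname = resname, chain = chain,
             resnum = resnum, icode = "", x = x, y = y, z = z,
             occupancy = 1, element = element, stringsAsFactors = FALSE)
}

# the dominant-arginine fixture used for hotspot-recovery properties:
# one strong phosphate salt bridge plus three weak distal polar contacts
dominant_arg_spec <- function(seed) {
  fixture_spec(
    planted_contacts = list(
      list(res = "ARG", moiety = "phosphate", dist = 2.9),
      list(res = "SER", moiety = "phosphate", dist = 5.5),
      list(res = "THR", moiety = "phosphate", dist = 6.0),
      list(res = "ASN", moiety = "phosphate", dist = 6.3)
    ),
    seed = seed
  )
}
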