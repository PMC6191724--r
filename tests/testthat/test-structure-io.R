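test_that("parsing types chains by residue content and flags non-complexes", {
  f <- tiny_complex_pdb()
  s <- parse_structure(f)
  expect_s3_class(s, "rnp_structure")
  expect_equal(unname(s$entities[c("A", "B")]), c("protein", "rna"))

  prot_only <- write_test_pdb(c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 1.5, 0, 0)
  ))
  expect_error(parse_structure(prot_only), "not a protein.RNA complex")

  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(parse_structure(empty), "empty")
  expect_error(parse_structure(tempfile()), "cannot read")
})

test_that("header metadata (method, resolution) is read when present", {
  f <- tiny_complex_pdb()
  txt <- readLines(f)
  writeLines(c("EXPDTA    X-RAY DIFFRACTION",
               "REMARK   2 RESOLUTION.    2.10 ANGSTROMS.", txt), f)
  s <- parse_structure(f)
  expect_equal(s$method, "xray")
  expect_equal(s$resolution, 2.10)
})

test_that("cleaning keeps NMR model 1 only with its exact atom count", {
  base <- c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "P", "A", "B", 1, 0, 8, 0),
    pdb_atom_line(4, "C1'", "A", "B", 1, 1, 8, 0)
  )
  shifted <- c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0.5, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 2.0, 0, 0),
    pdb_atom_line(3, "P", "A", "B", 1, 0.5, 8, 0),
    pdb_atom_line(4, "C1'", "A", "B", 1, 1.5, 8, 0)
  )
  f <- write_test_pdb(c("MODEL        1", base, "ENDMDL",
                        "MODEL        2", shifted, "ENDMDL"),
                      header = "EXPDTA    SOLUTION NMR")
  s <- parse_structure(f)
  expect_equal(s$n_models, 2L)
  cs <- clean_structure(s)
  expect_equal(cs$n_models, 1L)
  expect_equal(nrow(cs$atoms), 4L)
  expect_equal(cs$atoms$x[1], 0)      # model-1 coordinates retained
  expect_equal(cs$method, "nmr")
})

test_that("cleaning keeps the highest-occupancy altloc, first on ties", {
  lines <- c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CB", "ARG", "A", 1, 2.0, 1, 0, altloc = "A",
                  occ = 0.6),
    pdb_atom_line(4, "CB", "ARG", "A", 1, 2.2, 1, 0, altloc = "B",
                  occ = 0.4),
    pdb_atom_line(5, "CG", "ARG", "A", 1, 3.0, 1, 0, altloc = "A",
                  occ = 0.5),
    pdb_atom_line(6, "CG", "ARG", "A", 1, 3.2, 1, 0, altloc = "B",
                  occ = 0.5),
    pdb_atom_line(7, "P", "A", "B", 1, 0, 8, 0),
    pdb_atom_line(8, "C1'", "A", "B", 1, 1, 8, 0)
  )
  s <- clean_structure(parse_structure(write_test_pdb(lines)))
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 2.0)             # occupancy 0.6 wins
  cg <- s$atoms[s$atoms$elety == "CG", ]
  expect_equal(cg$x, 3.0)             # tie -> first in file order
})

test_that("hydrogens and waters are dropped; cleaning is idempotent", {
  lines <- c(
    pdb_atom_line(1, "N", "ARG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ARG", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "H", "ARG", "A", 1, 0.5, 0.5, 0, element = "H"),
    pdb_atom_line(4, "O", "HOH", "W", 1, 9, 9, 9, record = "HETATM"),
    pdb_atom_line(5, "P", "A", "B", 1, 0, 8, 0),
    pdb_atom_line(6, "C1'", "A", "B", 1, 1, 8, 0)
  )
  s <- clean_structure(parse_structure(write_test_pdb(lines)))
  expect_false(any(s$atoms$element == "H"))
  expect_false(any(s$atoms$resname == "HOH"))
  expect_identical(clean_structure(s)$atoms, s$atoms)
})

test_that("modified residues map to canonical parents", {
  lines <- c(
    pdb_atom_line(1, "N", "MSE", "A", 1, 0, 0, 0, record = "HETATM"),
    pdb_atom_line(2, "CA", "MSE", "A", 1, 1.5, 0, 0, record = "HETATM"),
    pdb_atom_line(3, "P", "PSU", "B", 1, 0, 8, 0, record = "HETATM"),
    pdb_atom_line(4, "C1'", "PSU", "B", 1, 1, 8, 0, record = "HETATM"),
    pdb_atom_line(5, "P", "A", "B", 2, 2, 8, 0),
    pdb_atom_line(6, "C1'", "A", "B", 2, 3, 8, 0)
  )
  s <- clean_structure(parse_structure(write_test_pdb(lines)))
  psu <- s$atoms[s$atoms$resname == "PSU", ][1, ]
  expect_equal(psu$kind, "nucleotide")
  expect_equal(psu$standard_parent, "U")
  expect_true(psu$is_modified)
  mse <- s$atoms[s$atoms$resname == "MSE", ][1, ]
  expect_equal(mse$standard_parent, "MET")
})

test_that("modified_base_fraction counts fractions with a closed boundary", {
  mk <- function(n_mod, n_total = 10) {
    rows <- do.call(rbind, lapply(seq_len(n_total), function(i) {
      resname <- if (i <= n_mod) "PSU" else "U"
      rbind(atom_row("P", resname, "B", i, 2 * i, 8, 0),
            atom_row("C1'", resname, "B", i, 2 * i + 1, 8, 0))
    }))
    structure_from_rows(rows)
  }
  expect_equal(modified_base_fraction(mk(0))$overall, 0.0)
  expect_equal(modified_base_fraction(mk(6))$overall, 0.6)
  # exactly half modified passes a "more than 50%" exclusion rule
  expect_equal(modified_base_fraction(mk(5))$overall, 0.5)
  prot <- structure_from_rows(rbind(atom_row("CA", "ARG", "A", 1, 0, 0, 0)))
  expect_error(modified_base_fraction(prot), "no RNA")
})

test_that("write/parse round trip preserves coordinates at PDB precision", {
  cx <- make_complex(fixture_spec(seed = 11))
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  back <- clean_structure(parse_structure(f))
  expect_equal(nrow(back$atoms), nrow(cx$atoms))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(cx$atoms[, c("x", "y", "z")]))), 5e-4)
  expect_identical(back$atoms$elety, cx$atoms$elety)
})

test_that("entity classification is invariant under chain reordering", {
  cx <- make_complex(fixture_spec(seed = 4))
  perm <- cx
  ord <- order(match(perm$atoms$chain, c("C", "P", "B")))
  perm$atoms <- perm$atoms[ord, ]
  expect_equal(chain_entities(perm)[sort(names(cx$entities))],
               cx$entities[sort(names(cx$entities))])
})
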