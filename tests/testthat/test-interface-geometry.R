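test_that("contact detection respects the cutoff boundary", {
  mk <- function(d) {
    structure_from_rows(rbind(
      atom_row("NH1", "ARG", "A", 1, 0, 0, 0),
      atom_row("CA", "ARG", "A", 1, 0, 2, 0),
      atom_row("OP1", "U", "B", 1, d, 0, 0),
      atom_row("C1'", "U", "B", 1, d + 1.5, 0, 0)
    ))
  }
  ct <- find_contacts(mk(3.9), cutoff = 4.0)
  expect_equal(sum(ct$rna_atom == "OP1"), 1L)
  ct2 <- find_contacts(mk(4.1), cutoff = 4.0)
  expect_false(any(ct2$rna_atom == "OP1" & ct2$protein_atom == "NH1" &
                     ct2$distance <= 4))
  expect_equal(nrow(find_contacts(mk(40), cutoff = 4.0)), 0L)
})

test_that("contacts carry correct moiety annotations", {
  s <- structure_from_rows(rbind(
    atom_row("NH1", "ARG", "A", 1, 0, 0, 0),
    atom_row("CA", "ARG", "A", 1, 0, 2.0, 0),
    atom_row("OP1", "U", "B", 1, 2.9, 0, 0),
    atom_row("O5'", "U", "B", 1, 2.9, 1.2, 0),
    atom_row("N3", "U", "B", 1, 2.9, -1.5, 0),
    atom_row("C1'", "U", "B", 1, 4.4, 0, 0)
  ))
  ct <- find_contacts(s, cutoff = 4.0)
  one <- function(p_atom, r_atom) {
    ct[ct$protein_atom == p_atom & ct$rna_atom == r_atom, ]
  }
  expect_equal(one("NH1", "OP1")$protein_moiety, "sidechain")
  expect_equal(one("NH1", "OP1")$rna_moiety, "phosphate")
  expect_equal(one("NH1", "O5'")$rna_moiety, "sugar")   # O5' is sugar
  expect_equal(one("NH1", "N3")$rna_moiety, "base")
  expect_equal(one("CA", "OP1")$protein_moiety, "backbone")
})

test_that("contact table equals a brute-force pair enumeration", {
  cx <- make_complex(fixture_spec(seed = 23))
  ct <- find_contacts(cx, cutoff = 4.5)
  pa <- cx$atoms[cx$atoms$chain == "P", ]
  ra <- cx$atoms[cx$atoms$chain != "P", ]
  n_brute <- 0L
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(ra))) {
      d <- sqrt(sum((as.numeric(pa[i, c("x", "y", "z")]) -
                       as.numeric(ra[j, c("x", "y", "z")]))^2))
      if (d <= 4.5) n_brute <- n_brute + 1L
    }
  }
  expect_equal(nrow(ct), n_brute)
  expect_false(any(duplicated(paste(ct$protein_chain, ct$protein_resnum,
                                    ct$protein_atom, ct$rna_chain,
                                    ct$rna_resnum, ct$rna_atom))))
})

test_that("moiety fractions partition every contact table", {
  for (seed in c(2, 9)) {
    ct <- find_contacts(make_complex(fixture_spec(seed = seed)))
    fr <- table(factor(ct$rna_moiety,
                       levels = c("phosphate", "sugar", "base"))) / nrow(ct)
    expect_equal(sum(fr), 1)
  }
})

test_that("scanning interface respects the 7 A boundary and exclusions", {
  mk <- function(d, resname = "LEU") {
    structure_from_rows(rbind(
      atom_row("CD1", resname, "A", 1, 0, 0, 0),
      atom_row("CA", resname, "A", 1, 0, 3, 0),
      atom_row("P", "U", "B", 1, d, 0, 0),
      atom_row("C1'", "U", "B", 1, d + 1.5, 0, 0)
    ))
  }
  expect_equal(nrow(interface_residues(mk(6.99))), 1L)
  expect_equal(nrow(interface_residues(mk(7.01))), 0L)
  # glycine is in the contact statistics but not the scanning list
  gly <- structure_from_rows(rbind(
    atom_row("CA", "GLY", "A", 1, 3, 0, 0),
    atom_row("P", "U", "B", 1, 0, 0, 0),
    atom_row("C1'", "U", "B", 1, -1.5, 0, 0)
  ))
  expect_equal(nrow(interface_residues(gly)), 0L)
  expect_gt(nrow(find_contacts(gly)), 0L)
  expect_equal(nrow(interface_residues(gly, exclude = character(0))), 1L)
})

test_that("SASA matches the closed form for isolated atoms and is additive", {
  one <- structure_from_rows(atom_row("P", "U", "B", 1, 0, 0, 0,
                                      element = "P"))
  got <- compute_sasa(one)$total
  expect_lt(abs(got - 4 * pi * (1.80 + 1.4)^2) / got, 0.01)

  two <- structure_from_rows(rbind(
    atom_row("P", "U", "B", 1, 0, 0, 0, element = "P"),
    atom_row("P", "U", "B", 2, 50, 0, 0, element = "P")
  ))
  expect_equal(compute_sasa(two)$total, 2 * got, tolerance = 1e-9)
})

test_that("a caged atom has near-zero SASA and dot density converges", {
  # icosahedral-ish cage of 50 atoms around the origin
  pts <- lapply(1:50, function(k) {
    z <- 1 - 2 * (k - 0.5) / 50
    r <- sqrt(1 - z^2)
    th <- pi * (3 - sqrt(5)) * k
    atom_row("C", "CAG", "X", k, 3.4 * r * cos(th), 3.4 * r * sin(th),
             3.4 * z)
  })
  cage <- structure_from_rows(do.call(rbind, c(
    list(atom_row("C", "CTR", "X", 0, 0, 0, 0)), pts)))
  per_atom <- compute_sasa(cage)$per_atom
  expect_lt(per_atom[1], 1e-6)

  cx <- make_complex(fixture_spec(seed = 3))
  t1 <- compute_sasa(cx, n_points = 960)$total
  t2 <- compute_sasa(cx, n_points = 1920)$total
  expect_lt(abs(t1 - t2) / t2, 0.005)
})

test_that("BSA is near zero for separated entities and symmetric", {
  apart <- make_complex(fixture_spec(seed = 5, planted_contacts = list()))
  b <- compute_bsa(apart, n_points = 480)
  expect_lt(abs(b$bsa), 5)

  cx <- make_complex(fixture_spec(seed = 5))
  b1 <- compute_bsa(cx, n_points = 480)
  expect_gt(b1$bsa, 50)
  expect_equal(b1$bsa,
               b1$sasa_protein_alone + b1$sasa_rna_alone - b1$sasa_complex)
  expect_gt(b1$bsa, -1)  # >= -epsilon sampling noise
  expect_error(compute_bsa(subset_chains(cx, "P")), "no rna chain")
})

test_that("frequency report aggregates counts, fractions and percentiles", {
  # percentile oracle: {1,2,3,4,5} at 20/80 -> 1.8, 4.2 by interpolation
  expect_equal(quantile(1:5, c(0.2, 0.8), type = 7, names = FALSE),
               c(1.8, 4.2))

  phos_only <- structure_from_rows(rbind(
    atom_row("NH1", "ARG", "A", 1, 0, 0, 0),
    atom_row("CA", "ARG", "A", 1, 0, 3, 0),
    atom_row("OP1", "U", "B", 1, 2.9, 0, 0),
    atom_row("C1'", "U", "B", 1, 7.5, 0, 0)
  ))
  fr <- frequency_report(list(find_contacts(phos_only)))
  expect_equal(unname(fr$backbone_fraction[1]), 1.0)

  tabs <- lapply(c(2, 9, 23), function(s) {
    find_contacts(make_complex(fixture_spec(seed = s)))
  })
  fr <- frequency_report(tabs)
  expect_equal(rowSums(fr$moiety_fractions), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(unname(fr$aa_mean["ARG"]), mean(fr$aa_counts[, "ARG"]))
  expect_true(all(fr$aa_counts >= 0))
  expect_error(frequency_report(list()), "non-empty")
})
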