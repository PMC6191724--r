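test_that("alanine truncation keeps exactly the backbone plus CB", {
  cx <- make_complex(fixture_spec(seed = 12))
  mut <- mutate_to_alanine(cx, "P", 1)     # the planted arginine
  res <- mut$atoms[mut$atoms$chain == "P" & mut$atoms$resnum == 1, ]
  expect_setequal(res$elety, c("N", "CA", "C", "O", "CB"))
  expect_true(all(res$resname == "ALA"))
  # every other residue is untouched, bit for bit
  other0 <- cx$atoms[!(cx$atoms$chain == "P" & cx$atoms$resnum == 1), ]
  other1 <- mut$atoms[!(mut$atoms$chain == "P" & mut$atoms$resnum == 1), ]
  expect_identical(unname(as.matrix(other1[, c("x", "y", "z")])),
                   unname(as.matrix(other0[, c("x", "y", "z")])))
  expect_error(mutate_to_alanine(cx, "B", 1), "non-amino-acid")
})

test_that("a missing CB is rebuilt at 1.52 A from CA", {
  s <- structure_from_rows(rbind(
    atom_row("N", "SER", "A", 1, 1.3, 0.6, 0),
    atom_row("CA", "SER", "A", 1, 0, 0, 0),
    atom_row("C", "SER", "A", 1, -0.6, -1.4, 0),
    atom_row("O", "SER", "A", 1, -1.8, -1.5, 0),
    atom_row("OG", "SER", "A", 1, 0.8, 0.5, 1.2),
    atom_row("P", "U", "B", 1, 5, 0, 0),
    atom_row("C1'", "U", "B", 1, 6.5, 0, 0)
  ))
  mut <- mutate_to_alanine(s, "A", 1)
  res <- mut$atoms[mut$atoms$chain == "A", ]
  cb <- res[res$elety == "CB", ]
  ca <- res[res$elety == "CA", ]
  expect_equal(nrow(cb), 1L)
  d <- sqrt(sum((as.numeric(cb[, c("x", "y", "z")]) -
                   as.numeric(ca[, c("x", "y", "z")]))^2))
  expect_equal(d, 1.52, tolerance = 1e-9)
})

test_that("glycine, proline and alanine targets are rejected", {
  rows <- rbind(
    atom_row("CA", "GLY", "A", 1, 0, 0, 0),
    atom_row("CA", "PRO", "A", 2, 4, 0, 0),
    atom_row("CA", "ALA", "A", 3, 8, 0, 0),
    atom_row("P", "U", "B", 1, 0, 6, 0),
    atom_row("C1'", "U", "B", 1, 1.5, 6, 0)
  )
  s <- structure_from_rows(rows)
  expect_error(mutate_to_alanine(s, "A", 1), "not varied")
  expect_error(mutate_to_alanine(s, "A", 2), "not varied")
  expect_error(mutate_to_alanine(s, "A", 3), "not varied")
})

test_that("delta-ln normalisation reproduces the worked example", {
  is <- interaction_scores(c(0.2, 0.4, 0.6))
  expect_equal(is, c(0.5, 1.0, 1.5))
  expect_equal(mean(is), 1)
  # negative values are excluded, zeros retained
  is2 <- interaction_scores(c(-0.1, 0, 0.4))
  expect_true(is.na(is2[1]))
  expect_equal(is2[2], 0)
  expect_equal(mean(is2, na.rm = TRUE), 1)
  expect_error(interaction_scores(c(-1, -2)), "no non-negative")
  expect_error(interaction_scores(c(0, 0)), "all delta-ln values are zero")
})

test_that("spot classification thresholds follow the IS definitions", {
  expect_equal(classify_spot(2.1), "hotspot")
  expect_equal(classify_spot(2.0), "warmspot")    # boundary included
  expect_equal(classify_spot(1.0), "other")
  expect_equal(classify_spot(c(0, 1.5, 3)), c("other", "warmspot", "hotspot"))
  expect_error(classify_spot(-0.2), "non-negative")
})

test_that("incremental variant scoring equals explicit mutate-and-rescore", {
  m <- test_model()
  cx <- make_complex(fixture_spec(seed = 17))
  scan <- alanine_scan(cx, m)
  rec <- scan$records[scan$records$class != "not_varied", ]
  for (k in seq_len(nrow(rec))) {
    mut <- mutate_to_alanine(cx, rec$chain[k], rec$resnum[k], rec$icode[k])
    full <- score_complex(mut, m)$dars
    expect_equal(rec$dars_ala[k], full, tolerance = 1e-9)
  }
  expect_equal(scan$dars_wt, score_complex(cx, m)$dars)
})

test_that("per-interface IS normalisation and classes are consistent", {
  m <- test_model()
  for (seed in c(7, 77, 777)) {
    scan <- alanine_scan(make_complex(fixture_spec(seed = seed)), m)
    r <- scan$records
    expect_equal(mean(r$is, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_equal(scan$n_positive, sum(!is.na(r$is)))
    neg <- r$class == "excluded_negative" & !is.na(r$class)
    expect_true(all(r$delta_ln[neg] < 0))
    expect_true(all(is.na(r$is[neg])))
    scored <- !is.na(r$is)
    expect_identical(r$class[scored], classify_spot(r$is[scored]))
  }
})

test_that("IS values are invariant under positive rescaling of the potential", {
  m <- test_model()
  m_scaled <- m
  m_scaled$energies <- 3.7 * m$energies
  cx <- make_complex(fixture_spec(seed = 19))
  s1 <- alanine_scan(cx, m)
  s2 <- alanine_scan(cx, m_scaled)
  expect_equal(s2$records$is, s1$records$is, tolerance = 1e-9)
})

test_that("interface glycines appear as not_varied records", {
  m <- test_model()
  # plant a glycine CB-less contact via a proline (excluded) and check the
  # not_varied bookkeeping on a fixture containing interface G/P
  cx <- make_complex(fixture_spec(
    planted_contacts = c(default_planted_contacts(),
                         list(list(res = "PRO", moiety = "phosphate",
                                   dist = 4.0))),
    seed = 33))
  scan <- alanine_scan(cx, m)
  nv <- scan$records[scan$records$class == "not_varied", ]
  expect_true("PRO" %in% nv$resname)
  expect_true(all(is.na(nv$is)))
})

test_that("correlation with experimental ddG behaves like Pearson r", {
  m <- test_model()
  scan <- alanine_scan(make_complex(fixture_spec(seed = 21)), m)
  r <- scan$records[!is.na(scan$records$is), ]
  ddg <- data.frame(chain = r$chain, resnum = r$resnum,
                    ddg = 2 * r$is)
  out <- correlate_with_ddg(scan, ddg)
  expect_equal(out$r, 1.0, tolerance = 1e-12)
  expect_equal(out$n_pairs, nrow(r))

  ddg$ddg <- -r$is
  expect_equal(correlate_with_ddg(scan, ddg)$r, -1.0, tolerance = 1e-12)

  # hand-computed 5-point oracle via the textbook formula
  x <- c(0.3, 1.1, 2.4, 0.8, 1.9)
  y <- c(0.5, 1.0, 3.1, 0.2, 2.2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ddg5 <- data.frame(chain = r$chain[1:5], resnum = r$resnum[1:5],
                     ddg = y)
  scan5 <- scan
  scan5$records$is[match(paste(ddg5$chain, ddg5$resnum),
                         paste(scan$records$chain,
                               scan$records$resnum))] <- x
  expect_equal(correlate_with_ddg(scan5, ddg5)$r, r_hand,
               tolerance = 1e-12)

  expect_error(correlate_with_ddg(scan, ddg[1:2, ]), "at least 3")
  expect_warning(correlate_with_ddg(scan, ddg5[1:4, ]), "fewer than 5")
  flat <- data.frame(chain = r$chain[1:5], resnum = r$resnum[1:5],
                     ddg = rep(1, 5))
  scan_flat <- scan
  scan_flat$records$is[!is.na(scan_flat$records$is)] <- 1
  expect_error(correlate_with_ddg(scan_flat, flat), "zero variance")
})

test_that("scan TSV export carries header metadata and all records", {
  m <- test_model()
  scan <- alanine_scan(make_complex(fixture_spec(seed = 13)), m)
  f <- tempfile(fileext = ".tsv")
  write_scan_tsv(scan, f)
  txt <- readLines(f)
  expect_true(any(grepl("^# AlaScanRNP", txt)))
  expect_true(any(grepl("cutoff=7.0", txt)))
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), nrow(scan$records))
  expect_true(all(c("chain", "resnum", "delta_ln", "is", "class") %in%
                    names(tab)))
})
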