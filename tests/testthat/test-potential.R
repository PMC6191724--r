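test_that("decoy generation is deterministic and keeps entities in contact", {
  cx <- make_complex(fixture_spec(seed = 31))
  d1 <- generate_decoys(cx, n = 5, seed = 99)
  d2 <- generate_decoys(cx, n = 5, seed = 99)
  for (k in 1:5) {
    expect_identical(d1[[k]]$atoms[, c("x", "y", "z")],
                     d2[[k]]$atoms[, c("x", "y", "z")])
  }
  prot <- as.matrix(cx$atoms[cx$atoms$chain == "P", c("x", "y", "z")])
  for (d in d1) {
    rna <- as.matrix(d$atoms[d$atoms$chain != "P", c("x", "y", "z")])
    dmin <- AlaScanRNP:::min_cross_distance(prot, rna)
    expect_gte(dmin, 3)
    expect_lte(dmin, 10)
  }
  expect_identical(generate_decoys(cx, n = 0, seed = 1), list())
})

test_that("training gives zero energy where nothing was observed and is deterministic", {
  cohort <- fixture_cohort(n = 3, seed_base = 61)
  m1 <- train_potential(cohort, n_decoys = 15, seed = 7)
  m2 <- train_potential(cohort, n_decoys = 15, seed = 7)
  expect_identical(m1$energies, m2$energies)
  # tryptophan never occurs in these fixtures -> all its cells stay 0
  expect_true(all(m1$energies["TRP", , , , ] == 0))
  expect_error(train_potential(list()), "non-empty")
})

test_that("native-enriched pair types get negative energies (count oracle)", {
  cohort <- fixture_cohort(n = 4, seed_base = 71)
  m <- train_potential(cohort, n_decoys = 20, seed = 13)
  # brute-force count of ARG sidechain / phosphate center pairs by bin
  counts <- numeric(m$n_bins)
  for (cx in cohort) {
    cen <- interaction_centers(cx)
    cp <- cen$protein[cen$protein$restype == "ARG" &
                        cen$protein$class == "sidechain", ]
    cr <- cen$rna[cen$rna$class == "phosphate", ]
    for (i in seq_len(nrow(cp))) {
      for (j in seq_len(nrow(cr))) {
        d <- sqrt(sum((as.numeric(cp[i, c("x", "y", "z")]) -
                         as.numeric(cr[j, c("x", "y", "z")]))^2))
        if (d < m$r_max) {
          b <- min(floor(d / m$bin_width) + 1, m$n_bins)
          counts[b] <- counts[b] + 1
        }
      }
    }
  }
  hot_bins <- which(counts >= 3)
  expect_gt(length(hot_bins), 0)
  for (b in hot_bins) {
    e_b <- m$energies["ARG", "sidechain", , "phosphate", b]
    expect_lt(min(e_b), 0)   # enriched bins favourable for >= 1 base type
  }
})

test_that("complex score equals a brute-force pair-sum oracle", {
  m <- test_model()
  cx <- make_complex(fixture_spec(seed = 41))
  got <- score_complex(cx, m)
  cen <- interaction_centers(cx)
  brute <- 0
  n_pairs <- 0L
  for (i in seq_len(nrow(cen$protein))) {
    for (j in seq_len(nrow(cen$rna))) {
      d <- sqrt(sum((as.numeric(cen$protein[i, c("x", "y", "z")]) -
                       as.numeric(cen$rna[j, c("x", "y", "z")]))^2))
      if (d < m$r_max) {
        b <- min(floor(d / m$bin_width) + 1, m$n_bins)
        brute <- brute + m$energies[cen$protein$restype[i],
                                    cen$protein$class[i],
                                    cen$rna$restype[j],
                                    cen$rna$class[j], b]
        n_pairs <- n_pairs + 1L
      }
    }
  }
  expect_equal(got$dars, brute, tolerance = 1e-12)
  expect_equal(got$n_pairs, n_pairs)
})

test_that("scores are rigid-motion invariant and additive over residues", {
  m <- test_model()
  cx <- make_complex(fixture_spec(seed = 42))
  s0 <- score_complex(cx, m)$dars
  R <- AlaScanRNP:::rot_z(31) %*% AlaScanRNP:::rot_x(57)
  moved <- cx
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2,
                                           c(-8, 13, 2), "+")
  expect_equal(score_complex(moved, m)$dars, s0, tolerance = 1e-9)

  # per-residue pair-energy sums add up to the total
  cen <- interaction_centers(cx)
  keys <- unique(paste(cen$protein$chain, cen$protein$resnum))
  per_res <- vapply(keys, function(k) {
    sel <- paste(cen$protein$chain, cen$protein$resnum) == k
    AlaScanRNP:::score_centers(cen$protein[sel, ], cen$rna, m)$dars
  }, numeric(1))
  expect_equal(sum(per_res), s0, tolerance = 1e-9)
})

test_that("distant chains give a zero score and empty selections error", {
  m <- test_model()
  apart <- make_complex(fixture_spec(seed = 6, planted_contacts = list()))
  sc <- score_complex(apart, m)
  expect_equal(sc$dars, 0)
  expect_equal(sc$n_pairs, 0L)
  expect_error(score_complex(subset_chains(apart, "P"), m), "no rna chain")
})

test_that("potential JSON serialisation round-trips", {
  m <- train_potential(fixture_cohort(n = 2, seed_base = 81),
                       n_decoys = 10, seed = 3)
  f <- tempfile(fileext = ".json")
  write_potential(m, f)
  m2 <- read_potential(f)
  expect_equal(m2$energies, m$energies)
  expect_equal(m2$bin_width, m$bin_width)
  expect_equal(m2$r_max, m$r_max)
  expect_equal(m2$training_meta$n_decoys, m$training_meta$n_decoys)
  # a round-tripped model scores identically
  cx <- make_complex(fixture_spec(seed = 82))
  expect_equal(score_complex(cx, m2)$dars, score_complex(cx, m)$dars)
})
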