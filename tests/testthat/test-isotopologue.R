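pf_meta <- compound_meta("2-pentylfuran", "C9H14O", odor_threshold = 0.006,
                         library_ri = 985)

test_that("cluster extraction zero-fills, truncates at 400 u, and rejects empty windows", {
  sp <- ei_spectrum("2-pentylfuran", 10,
                    data.frame(mz = c(138, 139), abundance = c(8910, 990)))
  cl <- extract_cluster(sp, pf_meta)
  expect_equal(cl$n, 9L)
  expect_equal(cl$abundances, c(8910, 990, rep(0, 8)))

  # all molecular-ion peaks absent
  sp2 <- ei_spectrum("2-pentylfuran", 10, data.frame(mz = 81, abundance = 100))
  expect_error(extract_cluster(sp2, pf_meta), "no molecular-ion",
               class = "camola_data_error")

  # window past the acquisition limit is truncated with reduced n
  big <- compound_meta("heavy", c(C = 29, H = 32, O = 1))  # M = 396
  sp3 <- ei_spectrum("heavy", 30, data.frame(mz = 396:400, abundance = rep(10, 5)))
  expect_warning(cl3 <- extract_cluster(sp3, big), "truncated")
  expect_equal(cl3$n, 4L)

  # analyzed-ion subset override
  cl4 <- extract_cluster(sp, pf_meta, n = 1)
  expect_equal(cl4$abundances, c(8910, 990))
})

test_that("cluster normalization reproduces raw isotope-ratio percentages", {
  cl <- isotope_cluster("2-pentylfuran", 138,
                        500 * c(91.2, 5.0, 0.0, 0.8, 0.9, 2.1, 0.0))
  expect_equal(as_percent(normalize_cluster(cl)),
               c(91.2, 5.0, 0.0, 0.8, 0.9, 2.1, 0.0))
  cl2 <- isotope_cluster("2-pentylfuran", 138,
                         500 * c(89.1, 9.9, 1.0, 0, 0, 0, 0))
  expect_equal(as_percent(normalize_cluster(cl2))[1], 89.1)
  # degenerate single-ion cluster
  expect_equal(as_percent(normalize_cluster(isotope_cluster("x", 100, c(7, 0, 0)))),
               c(100, 0, 0))
  expect_error(normalize_cluster(isotope_cluster("x", 100, c(0, 0))),
               "all-zero", class = "camola_data_error")
  # fractions sum to exactly 1 before rounding
  expect_equal(sum(as.numeric(normalize_cluster(cl))), 1)
})

test_that("correction matrix matches the single-carbon closed form and the expansion oracle", {
  one <- compound_meta("one-carbon", c(C = 1))
  M1 <- build_correction_matrix(one, n = 1, carbon_only = TRUE)
  expect_equal(unclass(M1), matrix(c(0.9893, 0.0107, 0, 1), 2, 2),
               ignore_attr = TRUE)

  # full-element columns equal the independent polynomial-expansion oracle
  M <- build_correction_matrix(pf_meta)
  for (k in c(0L, 3L, 9L)) {
    pat <- oracle_pattern(pf_meta$formula, k)
    expect_lt(max(abs(M[, k + 1] - pat[1:10])), 1e-12)
  }
  # fully labeled column in carbon-only mode is an identity tail
  Mc <- build_correction_matrix(pf_meta, carbon_only = TRUE)
  expect_equal(Mc[, 10], c(rep(0, 9), 1))
  expect_true(all(colSums(unclass(M)) <= 1 + 1e-12))
  expect_true(all(unclass(M) >= 0 & unclass(M) <= 1))
})

test_that("correction columns obey the carbon-count recurrence for C <= 12", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      counts <- random_formula(sample(2:12, 1))
      meta <- compound_meta("rand", counts)
      M <- build_correction_matrix(meta)
      for (k in 0:meta$carbon_count) {
        pat <- oracle_pattern(counts, k)
        pat <- c(pat, numeric(nrow(M)))[seq_len(nrow(M))]
        expect_lt(max(abs(M[, k + 1] - pat)), 1e-12)
      }
    }
  })
})

test_that("deconvolution inverts the forward model exactly in the noiseless case", {
  M <- build_correction_matrix(pf_meta)
  x0 <- c(0.6, 0.1, 0.05, 0.05, 0.05, 0.05, 0.03, 0.03, 0.02, 0.02)
  cl <- isotope_cluster("2-pentylfuran", 138, 1e6 * as.vector(unclass(M) %*% x0))
  d <- deconvolve(cl, M)
  expect_equal(as.numeric(d), x0, tolerance = 1e-6)
  expect_lt(attr(d, "relative_residual"), 1e-9)
})

test_that("deconvolving with the identity matrix equals plain normalization", {
  Id <- structure(diag(7), class = c("camola_correction_matrix", "matrix", "array"))
  withr::with_seed(99, {
    for (i in 1:50) {
      ab <- stats::runif(7, 0, 1e5)
      cl <- isotope_cluster("x", 138, ab)
      expect_equal(as.numeric(deconvolve(cl, Id)),
                   as.numeric(normalize_cluster(cl)), tolerance = 1e-9)
    }
  })
})

test_that("an ill-conditioned matrix raises a conditioning error", {
  bad <- structure(matrix(c(1, 1, 1, 1 + 1e-14), 2, 2),
                   class = c("camola_correction_matrix", "matrix", "array"))
  cl <- isotope_cluster("x", 100, c(10, 10))
  expect_error(deconvolve(cl, bad), "ill-conditioned", class = "camola_numeric_error")
  expect_error(deconvolve(cl, diag(3)), "conformable", class = "camola_numeric_error")
})

test_that("label summaries report counts above the reporting threshold", {
  d <- isotopomer_distribution(c(26, 66, 8, rep(0, 7)) / 100)
  s <- summarize_labels(d)
  expect_equal(s$pct_unlabeled, 26)
  expect_equal(s$labeled_carbon_numbers, c(1L, 2L))

  # no labeling -> no labeled carbon numbers
  s0 <- summarize_labels(isotopomer_distribution(c(1, 0, 0)))
  expect_equal(s0$labeled_carbon_numbers, integer(0))

  # uniform over 0..6 (~14.3% each) -> every k reported
  su <- summarize_labels(isotopomer_distribution(rep(1, 7) / 7))
  expect_equal(su$labeled_carbon_numbers, 1:6)
  # threshold sweep: raising the cutoff above 1/7 drops everything
  expect_equal(summarize_labels(isotopomer_distribution(rep(1, 7) / 7),
                                min_report_fraction = 15)$labeled_carbon_numbers,
               integer(0))
})

test_that("mean labeled carbons is the first moment of the distribution", {
  expect_equal(mean_labeled_carbons(isotopomer_distribution(c(1, 0, 0, 0, 0, 0, 0))), 0)
  expect_equal(mean_labeled_carbons(isotopomer_distribution(c(0, 0, 0, 0, 0, 0, 1))), 6)
  expect_equal(mean_labeled_carbons(isotopomer_distribution(c(0.5, 0, 0, 0, 0, 0, 0.5))), 3)
})
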