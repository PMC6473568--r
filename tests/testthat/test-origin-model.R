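test_that("hypothesis enumeration is exhaustive, deduplicated and deterministic", {
  mods <- rbind(precursor_module("glucose_C1", 1, TRUE),
                precursor_module("nonenal_C1", 1, FALSE))
  h <- enumerate_hypotheses(2, mods, max_modules = 2)
  expect_length(h, 3)
  expect_equal(vapply(h, `[[`, integer(1), "label_count"), c(0L, 1L, 2L))

  # C9 product with a richer inventory includes the single-module and
  # mixed-module routes
  mods9 <- rbind(precursor_module("glucose_C6", 6, TRUE),
                 precursor_module("nonenal_C9", 9, FALSE),
                 precursor_module("glucose_C4", 4, TRUE),
                 precursor_module("nonenal_C5", 5, FALSE))
  h9 <- enumerate_hypotheses(9, mods9, max_modules = 2)
  keys <- vapply(h9, function(x) paste(x$modules, collapse = "+"), character(1))
  expect_true("nonenal_C9" %in% keys)
  expect_true("glucose_C4+nonenal_C5" %in% keys)
  lab <- vapply(h9, `[[`, integer(1), "label_count")
  expect_equal(lab[keys == "nonenal_C9"], 0L)
  expect_equal(lab[keys == "glucose_C4+nonenal_C5"], 4L)
  # ordering: ascending label count, then lexicographic
  expect_true(all(diff(lab) >= 0))
  expect_false(any(duplicated(keys)))

  # product smaller than every module -> empty
  only_c2 <- precursor_module("cysteine_C2", 2, FALSE)
  expect_length(enumerate_hypotheses(1, only_c2), 0)

  # same inputs give identical order on repeat
  h9b <- enumerate_hypotheses(9, mods9, max_modules = 2)
  expect_identical(keys, vapply(h9b, function(x) paste(x$modules, collapse = "+"),
                                character(1)))
})

test_that("predicted distributions conserve weight at each label count", {
  mods <- rbind(precursor_module("glucose_C1", 1, TRUE),
                precursor_module("nonenal_C1", 1, FALSE))
  h <- enumerate_hypotheses(2, mods, max_modules = 2)
  p <- predict_distribution(h, c(1/3, 1/3, 1/3))
  expect_equal(as.numeric(p), rep(1/3, 3))
  # single hypothesis puts all mass at its label count
  h6 <- enumerate_hypotheses(6, precursor_module("glucose_C6", 6, TRUE))
  expect_equal(as.numeric(predict_distribution(h6, 1)), c(rep(0, 6), 1))
  # any simplex weight vector yields a valid distribution
  withr::with_seed(5, {
    mods_all <- default_precursor_modules("C")
    hs <- enumerate_hypotheses(5, mods_all, max_modules = 2)
    for (i in 1:20) {
      w <- random_simplex(length(hs))
      p <- predict_distribution(hs, w)
      expect_equal(sum(as.numeric(p)), 1)
      expect_true(all(as.numeric(p) >= 0))
    }
  })
  expect_error(predict_distribution(h, c(1, 0)), "length", class = "camola_data_error")
})

test_that("mixture fitting recovers identifiable weights and minimizes support", {
  mods <- default_precursor_modules("C")
  h <- enumerate_hypotheses(9, mods, max_modules = 3)
  # observed entirely unlabeled -> all weight on a label-0 hypothesis
  obs0 <- isotopomer_distribution(c(1, rep(0, 9)))
  f0 <- fit_mixture(obs0, h)
  expect_equal(f0$residual, 0)
  expect_equal(sum(f0$weights > 0), 1)
  expect_equal(h[[which(f0$weights > 0)]]$label_count, 0L)

  # recover weights pushed through the forward model (distinct label counts)
  sub <- h[match(unique(vapply(h, `[[`, integer(1), "label_count")),
                 vapply(h, `[[`, integer(1), "label_count"))]
  withr::with_seed(13, {
    w0 <- random_simplex(length(sub))
    obs <- predict_distribution(sub, w0)
    fit <- fit_mixture(obs, sub)
    expect_equal(unname(fit$weights), w0, tolerance = 1e-12)
    expect_equal(fit$residual, 0, tolerance = 1e-12)
  })

  # the printed three-isotopomer pattern maps to weights (0.87, 0.09, 0.04)
  obs_pt <- isotopomer_distribution(c(0.87, 0.09, 0.04, rep(0, 7)))
  fit_pt <- fit_mixture(obs_pt, h)
  expect_equal(fit_pt$residual, 0, tolerance = 1e-12)
  w <- fit_pt$weights[fit_pt$weights > 0]
  expect_equal(unname(w), c(0.87, 0.09, 0.04))
  expect_equal(vapply(h[fit_pt$weights > 0], `[[`, integer(1), "label_count"), 0:2)
})

test_that("mixture fitting matches brute-force grid search off the convex hull", {
  # hypotheses reach only label counts {0, 2}; observed mass at 1 cannot fit
  mods <- rbind(precursor_module("glucose_C2", 2, TRUE),
                precursor_module("nonenal_C2", 2, FALSE))
  h <- enumerate_hypotheses(2, mods, max_modules = 1)
  obs <- isotopomer_distribution(c(0.3, 0.4, 0.3))
  fit <- fit_mixture(obs, h)
  # dense grid over the 1-simplex as the independent optimum
  grid <- seq(0, 1, by = 1e-4)
  sse <- vapply(grid, function(a) {
    pred <- c(a, 0, 1 - a)
    sum((pred - as.numeric(obs))^2)
  }, numeric(1))
  best <- grid[which.min(sse)]
  expect_equal(unname(fit$weights[1]), best, tolerance = 1e-3)
  expect_equal(fit$residual, sqrt(min(sse)), tolerance = 1e-6)
})

test_that("origin calls reproduce the published narrative at default thresholds", {
  printed <- printed_summaries()
  call_of <- function(nm) {
    d <- isotopomer_distribution(printed[[nm]])
    classify_origin(summarize_labels(d))$category
  }
  unlabeled <- c("2-furanmethanol", "(E)-2-(1-pentenyl)-furan", "2-pentylfuran",
                 "ethanethiol", "1-methyl-5-mercaptotetrazole")
  for (nm in unlabeled) expect_equal(call_of(nm), "unlabeled-precursor-derived")
  for (nm in c("2-butyl-thiophene", "5-butyldihydro-2(3H)-furanone")) {
    expect_equal(call_of(nm), "glucose-derived")
  }
  for (nm in c("2-hexanoylfuran", "(E)-2-nonenal", "5-methyl-2(5H)-thiophenone",
               "4-pentyl-pyridine")) {
    expect_equal(call_of(nm), "mixed")
  }
  # a 50/50 split sits below both thresholds
  half <- summarize_labels(isotopomer_distribution(c(0.5, 0.5)))
  expect_equal(classify_origin(half)$category, "mixed")
})

test_that("origin classification is monotone in the unlabeled fraction", {
  call_of <- function(p) {
    classify_origin(summarize_labels(isotopomer_distribution(p)))$category
  }
  # deterministic boundary cases: once unlabeled, adding M+0 mass keeps it so
  p <- c(0.86, 0.07, 0.07, 0, 0, 0, 0)
  expect_equal(call_of(p), "unlabeled-precursor-derived")
  expect_equal(call_of(c(0.95, 0.02, 0.03, 0, 0, 0, 0)), "unlabeled-precursor-derived")
  withr::with_seed(21, {
    for (i in 1:50) {
      p <- random_simplex(7)
      c1 <- call_of(p)
      # push mass into p_0
      q <- p; q[1] <- q[1] + 0.2; q <- q / sum(q)
      c2 <- call_of(q)
      # never move away from the unlabeled call, never move into glucose
      expect_false(c1 == "unlabeled-precursor-derived" &&
                     c2 != "unlabeled-precursor-derived")
      expect_false(c1 %in% c("mixed", "unlabeled-precursor-derived") &&
                     c2 == "glucose-derived")
    }
  })
})
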