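#' Precursor carbon modules
#'
#' A precursor module is a contiguous block of carbons a precursor can
#' donate to a product skeleton: e.g. the intact C6 of labeled glucose, its
#' C1-C5 fragments, C1-C3 cysteine fragments, or C1-C9 fragments of the
#' lipid aldehyde. `labeled` marks modules stemming from the 13C6 tracer.
#'
#' @param name module name.
#' @param carbons number of carbons (>= 1).
#' @param labeled logical: does the module carry 13C labels?
#' @return one-row data frame with columns `name`, `carbons`, `labeled`.
#' @export
precursor_module <- function(name, carbons, labeled) {
  if (!is_count(carbons) || carbons < 1) stop_data("module '%s': carbons must be a positive integer", name)
  data.frame(name = name, carbons = as.integer(carbons), labeled = isTRUE(labeled),
             stringsAsFactors = FALSE)
}

#' Default precursor-module inventory per model system
#'
#' Mirrors the three reaction systems: A = labeled glucose +
#' (E)-2-nonenal; B = labeled glucose + cysteine; C = all three. Glucose
#' contributes labeled C1..C6 modules, cysteine unlabeled C1..C3, the
#' aldehyde unlabeled C1..C9.
#'
#' @param system `"A"`, `"B"` or `"C"`.
#' @return data frame of modules (one per row).
#' @export
default_precursor_modules <- function(system = c("A", "B", "C")) {
  system <- match.arg(system)
  glucose <- do.call(rbind, lapply(1:6, function(k)
    precursor_module(sprintf("glucose_C%d", k), k, TRUE)))
  cysteine <- do.call(rbind, lapply(1:3, function(k)
    precursor_module(sprintf("cysteine_C%d", k), k, FALSE)))
  nonenal <- do.call(rbind, lapply(1:9, function(k)
    precursor_module(sprintf("nonenal_C%d", k), k, FALSE)))
  switch(system,
         A = rbind(glucose, nonenal),
         B = rbind(glucose, cysteine),
         C = rbind(glucose, cysteine, nonenal))
}

#' Enumerate pathway hypotheses for a product skeleton
#'
#' A pathway hypothesis is a multiset of at most `max_modules` precursor
#' modules whose carbons sum to the product's carbon count; its label count
#' is the summed size of its labeled modules. Modules may repeat.
#' Hypotheses are deduplicated and returned in a deterministic order:
#' ascending label count, then lexicographically by the sorted module
#' names.
#'
#' @param product_carbons carbon count of the product (>= 1).
#' @param modules data frame of modules, see [precursor_module()].
#' @param max_modules largest number of modules per hypothesis (default 3:
#'   mechanisms beyond two building blocks plus a one-carbon fragment are
#'   not entertained).
#' @return list of hypotheses; each is a list with `modules` (character),
#'   `carbons` (integer), `label_count`, `product_carbons`.
#' @export
#' @examples
#' mods <- rbind(precursor_module("glucose_C1", 1, TRUE),
#'               precursor_module("nonenal_C1", 1, FALSE))
#' length(enumerate_hypotheses(2, mods, max_modules = 2))  # 3
enumerate_hypotheses <- function(product_carbons, modules, max_modules = 3) {
  if (!is_count(product_carbons) || product_carbons < 1) {
    stop_data("product_carbons must be a positive integer")
  }
  if (!nrow(modules)) stop_data("module list is empty")
  res <- list()
  nm <- nrow(modules)
  recurse <- function(start, remaining, chosen) {
    if (remaining == 0L) {
      res[[length(res) + 1L]] <<- chosen
      return(invisible())
    }
    if (length(chosen) >= max_modules) return(invisible())
    for (i in start:nm) {
      if (modules$carbons[i] <= remaining) {
        recurse(i, remaining - modules$carbons[i], c(chosen, i))
      }
    }
    invisible()
  }
  recurse(1L, as.integer(product_carbons), integer(0))
  hyps <- lapply(res, function(idx) {
    mods <- modules[idx, , drop = FALSE]
    o <- order(mods$name)
    list(
      modules = mods$name[o],
      carbons = mods$carbons[o],
      labeled = mods$labeled[o],
      label_count = as.integer(sum(mods$carbons[mods$labeled])),
      product_carbons = as.integer(product_carbons)
    )
  })
  key <- vapply(hyps, function(h) paste(h$modules, collapse = "+"), character(1))
  hyps <- hyps[!duplicated(key)]
  key <- key[!duplicated(key)]
  ord <- order(vapply(hyps, `[[`, integer(1), "label_count"), key)
  hyps[ord]
}

#' Predict the label-count distribution of a pathway mixture
#'
#' Given mixture weights over hypotheses, the predicted isotopomer
#' fraction at k labeled carbons is the total weight of hypotheses with
#' label count k.
#'
#' @param hypotheses list from [enumerate_hypotheses()].
#' @param weights non-negative weights summing to 1, one per hypothesis.
#' @return an [isotopomer_distribution()] of length `product_carbons + 1`.
#' @export
predict_distribution <- function(hypotheses, weights) {
  if (length(weights) != length(hypotheses)) {
    stop_data("weight vector length %d != %d hypotheses",
              length(weights), length(hypotheses))
  }
  if (any(weights < -1e-12)) stop_data("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8) stop_data("weights must sum to 1")
  n <- hypotheses[[1]]$product_carbons
  p <- numeric(n + 1L)
  for (i in seq_along(hypotheses)) {
    k <- hypotheses[[i]]$label_count
    p[k + 1L] <- p[k + 1L] + weights[i]
  }
  isotopomer_distribution(p)
}

# Euclidean projection of v onto the probability simplex (sort algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Fit pathway mixture weights to an observed distribution
#'
#' Finds non-negative weights summing to 1 that minimize the squared
#' distance between the predicted and observed label-count distributions.
#' Because hypotheses with the same label count are spectrally
#' indistinguishable, the optimal total weight per label count is the
#' Euclidean projection of the observed fractions (at attainable counts)
#' onto the simplex; each total is then assigned to the first hypothesis
#' with that label count in enumeration order, giving the minimum-support
#' solution among exact fits with deterministic tie-breaking.
#'
#' @param observed an [isotopomer_distribution()].
#' @param hypotheses list from [enumerate_hypotheses()] (>= 1 hypothesis).
#' @return list with `weights` (named by hypothesis), `fitted`
#'   ([isotopomer_distribution()]) and `residual` (Euclidean norm).
#' @export
fit_mixture <- function(observed, hypotheses) {
  stopifnot(inherits(observed, "camola_distribution"))
  if (!length(hypotheses)) stop_data("need at least one hypothesis")
  p <- as.numeric(observed)
  n <- hypotheses[[1]]$product_carbons
  if (length(p) != n + 1L) {
    stop_data("observed distribution length %d != product carbons + 1 (%d)",
              length(p), n + 1L)
  }
  labels <- vapply(hypotheses, `[[`, integer(1), "label_count")
  ks <- sort(unique(labels))
  W <- project_simplex(p[ks + 1L])
  weights <- numeric(length(hypotheses))
  for (j in seq_along(ks)) {
    first <- which(labels == ks[j])[1]
    weights[first] <- W[j]
  }
  names(weights) <- vapply(hypotheses, function(h) paste(h$modules, collapse = "+"),
                           character(1))
  fitted <- predict_distribution(hypotheses, weights)
  list(weights = weights,
       fitted = fitted,
       residual = sqrt(sum((as.numeric(fitted) - p)^2)))
}

#' Origin-call thresholds
#'
#' Numeric thresholds that translate a label summary into the qualitative
#' origin language ("mainly", "obviously", "stemmed from"): a compound is
#' called unlabeled-precursor-derived when the unlabeled fraction reaches
#' `unlabeled` percent, glucose-derived when the fully-labeled fraction
#' reaches `fully_labeled` percent or the summed labeled fraction reaches
#' `labeled_sum` percent, and mixed otherwise.
#'
#' @param unlabeled percent of M+0 for an unlabeled-precursor call
#'   (default 85).
#' @param fully_labeled percent at k = n for a glucose call (default 50).
#' @param labeled_sum summed labeled percent for a glucose call
#'   (default 80).
#' @return a named list of class `camola_origin_thresholds`.
#' @export
origin_thresholds <- function(unlabeled = 85, fully_labeled = 50, labeled_sum = 80) {
  structure(list(unlabeled = unlabeled, fully_labeled = fully_labeled,
                 labeled_sum = labeled_sum),
            class = "camola_origin_thresholds")
}

#' Classify the carbon origin of a compound
#'
#' Applies [origin_thresholds()] to a label summary. Precedence: the
#' unlabeled call is checked first, so increasing the unlabeled fraction
#' can never move a compound away from the unlabeled-precursor category
#' (monotonicity).
#'
#' @param summary a [summarize_labels()] result.
#' @param thresholds an [origin_thresholds()] object.
#' @return list of class `camola_origin_call` with `category` (one of
#'   `"unlabeled-precursor-derived"`, `"glucose-derived"`, `"mixed"`),
#'   `pct_unlabeled`, `pct_fully_labeled`, `pct_labeled_sum`.
#' @export
classify_origin <- function(summary, thresholds = origin_thresholds()) {
  stopifnot(inherits(summary, "camola_label_summary"))
  p <- summary$fractions
  n <- length(p) - 1L
  pct0 <- 100 * p[1]
  pct_full <- 100 * p[n + 1L]
  pct_lab <- 100 * (1 - p[1])
  # unlabeled call uses >= so a compound sitting exactly at the threshold is
  # called; glucose calls are strict so an even 50/50 split stays "mixed"
  category <- if (pct0 >= thresholds$unlabeled) {
    "unlabeled-precursor-derived"
  } else if (pct_full > thresholds$fully_labeled || pct_lab > thresholds$labeled_sum) {
    "glucose-derived"
  } else {
    "mixed"
  }
  structure(
    list(category = category, pct_unlabeled = pct0,
         pct_fully_labeled = pct_full, pct_labeled_sum = pct_lab),
    class = "camola_origin_call"
  )
}

#' @export
print.camola_origin_call <- function(x, ...) {
  cat(sprintf("<camola_origin_call> %s (unlabeled %.1f%%, fully labeled %.1f%%)\n",
              x$category, x$pct_unlabeled, x$pct_fully_labeled))
  invisible(x)
}
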