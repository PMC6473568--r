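#' Molecular-ion isotopologue cluster
#'
#' Raw abundances of the contiguous window M+0..M+n around a compound's
#' molecular ion. In a carbon-module labeling experiment the window spans
#' one mass unit per potentially labeled carbon, so `n` defaults to the
#' compound's carbon count.
#'
#' @param compound_id compound identifier.
#' @param base_mz nominal m/z of M+0.
#' @param abundances non-negative abundances at `base_mz + 0:n`.
#' @return an object of class `camola_cluster`.
#' @export
isotope_cluster <- function(compound_id, base_mz, abundances) {
  abundances <- as.numeric(abundances)
  if (!length(abundances)) stop_data("cluster '%s': empty abundance vector", compound_id)
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    stop_data("cluster '%s': abundances must be finite and >= 0", compound_id)
  }
  structure(
    list(compound_id = compound_id, base_mz = as.integer(base_mz),
         abundances = abundances, n = length(abundances) - 1L),
    class = "camola_cluster"
  )
}

#' @export
print.camola_cluster <- function(x, ...) {
  cat(sprintf("<camola_cluster> %s  m/z %d-%d\n", x$compound_id,
              x$base_mz, x$base_mz + x$n))
  print(stats::setNames(x$abundances, x$base_mz + 0:x$n))
  invisible(x)
}

#' Extract the molecular-ion cluster from a spectrum
#'
#' Copies the abundances at `M+0 .. M+n` (missing m/z get 0) where M+0 is
#' the compound's nominal mass. A window that would exceed the 400 u
#' acquisition limit is truncated with a warning. Peaks at or below the
#' noise floor are zeroed.
#'
#' @param spectrum a [ei_spectrum()] object.
#' @param meta the compound's [compound_meta()].
#' @param n window width minus one; defaults to the carbon count. Set a
#'   smaller value to restrict the analysis to a subset of ions.
#' @param noise_floor absolute abundance below which signals are treated
#'   as noise (default 0: keep everything).
#' @return an [isotope_cluster()].
#' @export
extract_cluster <- function(spectrum, meta, n = NULL, noise_floor = 0) {
  stopifnot(inherits(spectrum, "camola_spectrum"), inherits(meta, "camola_compound"))
  if (is.null(n)) n <- meta$carbon_count
  base <- meta$nominal_mass
  if (base + n > 400L) {
    n_new <- max(0L, 400L - base)
    warning(sprintf("'%s': window %d-%d exceeds the 400 u range; truncated to n = %d",
                    meta$name, base, base + n, n_new))
    n <- n_new
  }
  ab <- numeric(n + 1L)
  hit <- match(base + 0:n, spectrum$peaks$mz)
  ab[!is.na(hit)] <- spectrum$peaks$abundance[hit[!is.na(hit)]]
  ab[ab <= noise_floor & ab > 0] <- 0
  if (all(ab == 0)) {
    stop_data("'%s': no molecular-ion signal at m/z %d-%d", meta$name, base, base + n)
  }
  isotope_cluster(meta$name, base, ab)
}

#' Isotopomer distribution
#'
#' Fractions `p_0 .. p_n` of molecular species carrying 0..n labeled
#' carbons, summing to 1.
#'
#' @param fractions non-negative vector summing to 1 (renormalized if it
#'   deviates by < 1e-6, rejected beyond that).
#' @return an object of class `camola_distribution` (a numeric vector).
#' @export
isotopomer_distribution <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (any(!is.finite(fractions)) || any(fractions < -1e-12)) {
    stop_data("fractions must be finite and >= 0")
  }
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (s <= 0) stop_data("fractions sum to zero: undefined distribution")
  fractions <- fractions / s
  structure(fractions, class = "camola_distribution")
}

#' @export
print.camola_distribution <- function(x, ...) {
  cat("<camola_distribution> % by number of labeled carbons\n")
  print(stats::setNames(round_half_up(100 * as.numeric(x), 1),
                        paste0("k=", seq_along(x) - 1L)))
  invisible(x)
}

#' Normalize a cluster into isotope ratios
#'
#' The default, correction-free view of the data: each fraction is the ion
#' abundance divided by the summed abundance of the window, exactly the
#' isotope-ratio percentages of the published tables. Natural-abundance
#' deconvolution is the separate, opt-in [deconvolve()].
#'
#' @param cluster an [isotope_cluster()].
#' @return an [isotopomer_distribution()].
#' @export
#' @examples
#' cl <- isotope_cluster("2-pentylfuran", 138, c(45600, 2500, 0, 400, 450, 1050, 0))
#' as_percent(normalize_cluster(cl))  # 91.2% at M+0
normalize_cluster <- function(cluster) {
  stopifnot(inherits(cluster, "camola_cluster"))
  s <- sum(cluster$abundances)
  if (s <= 0) stop_data("'%s': all-zero cluster has no distribution", cluster$compound_id)
  isotopomer_distribution(cluster$abundances / s)
}

#' Percent view of a distribution
#'
#' @param dist an [isotopomer_distribution()].
#' @param digits decimals (default 1, half-up, the report precision).
#' @return numeric vector of percentages.
#' @export
as_percent <- function(dist, digits = 1) {
  round_half_up(100 * as.numeric(dist), digits)
}

#' Natural isotope abundance table
#'
#' Per-element mass-shift polynomials (probability of +0, +1, +2 ... u per
#' atom) for C, H, N, O and S at natural abundance. Heavy-isotope levels:
#' 13C 1.07%, 2H 0.0115%, 15N 0.364%, 17O 0.038%, 18O 0.205%, 33S 0.75%,
#' 34S 4.25%, 36S 0.01%.
#'
#' @return named list of numeric vectors, each summing to 1.
#' @export
isotope_abundances <- function() {
  raw <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  lapply(raw, function(v) v / sum(v))
}

#' Natural-abundance correction matrix
#'
#' Square matrix with entry (i, k) = probability that a molecule carrying
#' exactly `k` tracer 13C atoms is observed at M+i. Column `k` is the
#' binomial natural-13C pattern of the remaining `C - k` carbons convolved
#' with the isotope polynomials of the molecule's H, N, O and S atoms, then
#' shifted down by `k` rows and truncated to the M+0..M+n window (so
#' columns sum to <= 1, and to 1 when the window is wide enough). Tracer
#' carbons are taken as isotopically pure 13C.
#'
#' @param meta the compound's [compound_meta()].
#' @param abundances per-element isotope table, see [isotope_abundances()].
#' @param n window width minus one (default: carbon count).
#' @param carbon_only if `TRUE`, only carbon isotopes contribute (the
#'   closed-form case used for validation); default `FALSE`.
#' @return an `(n+1) x (n+1)` matrix of class `camola_correction_matrix`.
#' @export
build_correction_matrix <- function(meta, abundances = isotope_abundances(),
                                    n = NULL, carbon_only = FALSE) {
  stopifnot(inherits(meta, "camola_compound"))
  if (is.null(n)) n <- meta$carbon_count
  C <- meta$carbon_count
  p13 <- abundances$C[2] / sum(abundances$C)
  hetero <- 1
  if (!carbon_only) {
    for (el in c("H", "N", "O", "S")) {
      cnt <- meta$formula[[el]]
      if (cnt > 0) hetero <- conv_poly(hetero, conv_pow(abundances[[el]], cnt))
    }
  }
  M <- matrix(0, nrow = n + 1L, ncol = n + 1L)
  for (k in 0:n) {
    if (k > C) stop_numeric("cannot label %d carbons: compound has %d", k, C)
    carbon_part <- stats::dbinom(0:(C - k), C - k, p13)
    pattern <- conv_poly(carbon_part, hetero)
    rows <- k:n
    vals <- pattern[seq_len(length(rows))]
    vals[is.na(vals)] <- 0
    M[rows + 1L, k + 1L] <- vals
  }
  structure(M, class = c("camola_correction_matrix", "matrix", "array"))
}

#' Deconvolve natural abundance from a cluster
#'
#' Solves `M x ~ abundances` under `x >= 0` by non-negative least squares
#' and normalizes `x` into tracer-isotopomer fractions. With the identity
#' matrix this reduces exactly to [normalize_cluster()]. The residual norm
#' and the relative residual are attached as attributes.
#'
#' @param cluster an [isotope_cluster()].
#' @param matrix a [build_correction_matrix()] result conformable with the
#'   cluster.
#' @param max_condition conditioning guard: a matrix with 2-norm condition
#'   number above this raises an error naming the estimate (default 1e8).
#' @return an [isotopomer_distribution()] with attributes `residual`
#'   (norm of `M x - b`), `relative_residual`, and `raw` (unnormalized x).
#' @export
deconvolve <- function(cluster, matrix, max_condition = 1e8) {
  stopifnot(inherits(cluster, "camola_cluster"))
  M <- unclass(matrix)
  b <- cluster$abundances
  if (!is.matrix(M) || nrow(M) != length(b) || ncol(M) != length(b)) {
    stop_numeric("correction matrix (%dx%d) not conformable with cluster of length %d",
                 NROW(M), NCOL(M), length(b))
  }
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop_numeric("correction matrix is ill-conditioned (condition estimate %.3g)", kap)
  }
  fit <- pracma::lsqnonneg(M, b)
  x <- fit$x
  if (sum(x) <= 0) stop_numeric("'%s': deconvolution returned an all-zero solution",
                                cluster$compound_id)
  out <- isotopomer_distribution(x / sum(x))
  attr(out, "residual") <- sqrt(sum((M %*% x - b)^2))
  attr(out, "relative_residual") <- attr(out, "residual") / sqrt(sum(b^2))
  attr(out, "raw") <- x
  out
}

#' Summarize labeled and unlabeled proportions
#'
#' Condenses a distribution into the report form of the isotopomer
#' proportion tables: the unlabeled percentage (`100 p_0`), the percentage
#' at each reported label count, and the list of label counts `k >= 1`
#' whose percentage reaches `min_report_fraction`.
#'
#' @param dist an [isotopomer_distribution()].
#' @param min_report_fraction smallest percentage at which a label count is
#'   listed (default 2, consistent with the smallest values the report
#'   tables print).
#' @return an object of class `camola_label_summary`: list with
#'   `pct_unlabeled`, `pct_labeled_by_k` (named by k), and
#'   `labeled_carbon_numbers` (ascending), plus the full `fractions`.
#' @export
summarize_labels <- function(dist, min_report_fraction = 2) {
  stopifnot(inherits(dist, "camola_distribution"))
  pct <- 100 * as.numeric(dist)
  n <- length(pct) - 1L
  ks <- integer(0)
  if (n >= 1L) {
    ks <- which(pct[-1] >= min_report_fraction - 1e-9)
  }
  structure(
    list(
      pct_unlabeled = pct[1],
      pct_labeled_by_k = stats::setNames(pct[ks + 1L], ks),
      labeled_carbon_numbers = as.integer(ks),
      fractions = as.numeric(dist)
    ),
    class = "camola_label_summary"
  )
}

#' @export
print.camola_label_summary <- function(x, ...) {
  cat(sprintf("<camola_label_summary> unlabeled %.1f%%; labeled k = {%s}\n",
              x$pct_unlabeled,
              paste(x$labeled_carbon_numbers, collapse = ", ")))
  invisible(x)
}

#' Mean number of labeled carbons
#'
#' The first moment `sum(k * p_k)` of an isotopomer distribution.
#'
#' @param dist an [isotopomer_distribution()].
#' @return a single number in `[0, n]`.
#' @export
mean_labeled_carbons <- function(dist) {
  stopifnot(inherits(dist, "camola_distribution"))
  p <- as.numeric(dist)
  sum((seq_along(p) - 1L) * p)
}
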