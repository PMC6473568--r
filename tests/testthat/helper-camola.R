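# Shared fixtures and independent oracles for the test suite.

# Random point on the k-simplex.
random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Random small CHNOS formula with n_carbons carbons.
random_formula <- function(n_carbons) {
  c(C = n_carbons,
    H = sample(0:(2 * n_carbons + 2), 1),
    N = sample(0:2, 1),
    O = sample(0:3, 1),
    S = sample(0:2, 1))
}

# Independent isotope-pattern oracle: expands the molecular mass-shift
# polynomial one atom at a time with stats::convolve (open convolution),
# never via dbinom or the package's conv helpers.
oracle_pattern <- function(counts, n_labeled, abundances = isotope_abundances(),
                           carbon_only = FALSE) {
  pat <- 1
  mult <- function(p, q) {
    if (length(p) == 1) return(p * q)
    if (length(q) == 1) return(p * q)
    stats::convolve(p, rev(q), type = "open")
  }
  for (i in seq_len(counts[["C"]] - n_labeled)) pat <- mult(pat, abundances$C)
  if (!carbon_only) {
    for (el in c("H", "N", "O", "S")) {
      for (i in seq_len(counts[[el]])) pat <- mult(pat, abundances[[el]])
    }
  }
  # shift by the labeled carbons
  c(rep(0, n_labeled), pat)
}

# Printed labeling splits of the three model systems (analyzed-ion
# percentages; censored "<"/">" entries at their bounds).
printed_summaries <- function() {
  list(
    "2-furanmethanol" = c(90, 10),
    "(E)-2-(1-pentenyl)-furan" = c(89, 10),
    "2-hexanoylfuran" = c(64, 11, 4, 7, 0, 4, 8),
    "(E)-2-nonenal" = c(26, 66, 8),
    "2-pentylfuran" = c(89, 11),
    "ethanethiol" = c(92, 0, 5),
    "5-methyl-2(5H)-thiophenone" = c(42, 34, 12, 7),
    "2-butyl-thiophene" = c(19, 13, 16, 12, 12, 14, 13),
    "1-methyl-5-mercaptotetrazole" = c(93, 7),
    "5-butyldihydro-2(3H)-furanone" = c(7, 6, 7, 29, 20, 15, 16),
    "4-pentyl-pyridine" = c(71, 26),
    "2-pentyl-thiophene" = c(87, 9, 4)
  )
}

tiny_ladder <- function() {
  alkane_ladder(6:12, c(2, 4.5, 7.5, 10, 12, 14.5, 17))
}
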