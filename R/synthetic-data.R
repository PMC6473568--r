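#' Forward-simulate one molecular-ion cluster
#'
#' Generates the raw abundance window a GC-MS run would record for a
#' compound whose tracer-isotopomer mixture is known: the true fractions
#' are pushed through the natural-abundance correction matrix (so each
#' k-labeled species contributes its full isotope envelope), scaled to a
#' total signal, and perturbed by the chosen noise model. Multiplicative
#' log-normal noise is the default (EI peak-area repeatability is
#' proportional); `"counting"` draws Poisson counts for low-signal work;
#' `"none"` is exact.
#'
#' @param meta the compound's [compound_meta()].
#' @param true_fractions tracer-isotopomer fractions (simplex, length
#'   `n + 1`).
#' @param total_signal summed expected abundance (arbitrary units,
#'   default 1e6).
#' @param noise `"proportional"`, `"counting"` or `"none"`.
#' @param cv coefficient of variation of the proportional noise
#'   (default 0.05).
#' @param seed integer seed; the global RNG state is left untouched.
#' @param correction apply the natural-abundance envelope (default `TRUE`).
#'   With `FALSE` the expected window is directly proportional to the true
#'   fractions.
#' @param carbon_only passed to [build_correction_matrix()].
#' @param abundances isotope table, see [isotope_abundances()].
#' @return an [isotope_cluster()] with attribute `truth` (the input
#'   fractions) and `expected` (the noiseless window).
#' @export
generate_cluster <- function(meta, true_fractions, total_signal = 1e6,
                             noise = c("proportional", "counting", "none"),
                             cv = 0.05, seed = NULL, correction = TRUE,
                             carbon_only = FALSE,
                             abundances = isotope_abundances()) {
  noise <- match.arg(noise)
  f <- as.numeric(true_fractions)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop_data("'%s': true fractions must lie on the simplex", meta$name)
  }
  n <- length(f) - 1L
  if (correction) {
    M <- build_correction_matrix(meta, abundances = abundances, n = n,
                                 carbon_only = carbon_only)
    mu <- total_signal * as.numeric(unclass(M) %*% f)
  } else {
    mu <- total_signal * f
  }
  draw <- function() {
    switch(noise,
           none = mu,
           proportional = {
             sdlog <- sqrt(log(1 + cv^2))
             mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
           },
           counting = stats::rpois(length(mu), mu))
  }
  ab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  cl <- isotope_cluster(meta$name, meta$nominal_mass, ab)
  attr(cl, "truth") <- f
  attr(cl, "expected") <- mu
  cl
}

#' Default compound panel
#'
#' The volatiles whose labeling patterns the model systems are built
#' around, with formulas, odor thresholds where known, and DB-5 library
#' retention indices.
#'
#' @return named list of [compound_meta()] objects.
#' @export
default_compound_panel <- function() {
  metas <- list(
    compound_meta("2-furanmethanol", "C5H6O2", library_ri = 873),
    compound_meta("2-pentylfuran", "C9H14O", odor_threshold = 0.006, library_ri = 985),
    compound_meta("(E)-2-(1-pentenyl)-furan", "C9H12O", library_ri = 1060),
    compound_meta("2-hexanoylfuran", "C10H14O2", library_ri = 1283),
    compound_meta("(E)-2-nonenal", "C9H16O", library_ri = 1150),
    compound_meta("ethanethiol", "C2H6S", library_ri = 790),
    compound_meta("5-methyl-2(5H)-thiophenone", "C5H6OS", library_ri = 1024),
    compound_meta("2-butyl-thiophene", "C8H12S", library_ri = 1045),
    compound_meta("1-methyl-5-mercaptotetrazole", "C2H4N4S", library_ri = 1071),
    compound_meta("5-butyldihydro-2(3H)-furanone", "C8H14O2", library_ri = 1218),
    compound_meta("4-pentyl-pyridine", "C10H15N", library_ri = 1242),
    compound_meta("2-pentyl-thiophene", "C9H14S", library_ri = 1160)
  )
  stats::setNames(metas, vapply(metas, `[[`, character(1), "name"))
}

#' Default true isotopomer fractions per system
#'
#' The study conditions the simulator emulates: per reaction system
#' (A = glucose + nonenal, B = glucose + cysteine, C = all three), each
#' compound's tracer-isotopomer mixture, matching the labeling splits the
#' model systems produce. Fractions are over `k = 0..carbon_count`.
#'
#' @param panel a compound panel, see [default_compound_panel()].
#' @return nested list `fractions[[system]][[compound]]` of simplex vectors.
#' @export
default_true_fractions <- function(panel = default_compound_panel()) {
  pad <- function(v, n) {
    out <- numeric(n + 1L)
    out[seq_along(v)] <- v
    out / sum(out)
  }
  nc <- function(name) panel[[name]]$carbon_count
  list(
    A = list(
      "2-furanmethanol" = pad(c(90, 10), nc("2-furanmethanol")),
      "(E)-2-(1-pentenyl)-furan" = pad(c(89, 10), nc("(E)-2-(1-pentenyl)-furan")),
      "2-hexanoylfuran" = pad(c(64, 11, 4, 7, 0, 4, 8), nc("2-hexanoylfuran")),
      "(E)-2-nonenal" = pad(c(26, 66, 8), nc("(E)-2-nonenal")),
      "2-pentylfuran" = pad(c(89, 11), nc("2-pentylfuran"))
    ),
    B = list(
      "ethanethiol" = pad(c(92, 0, 5), nc("ethanethiol")),
      "5-methyl-2(5H)-thiophenone" = pad(c(42, 34, 12, 7), nc("5-methyl-2(5H)-thiophenone")),
      "2-butyl-thiophene" = pad(c(19, 13, 16, 12, 12, 14, 13), nc("2-butyl-thiophene")),
      "1-methyl-5-mercaptotetrazole" = pad(c(93, 7), nc("1-methyl-5-mercaptotetrazole")),
      "5-butyldihydro-2(3H)-furanone" = pad(c(7, 6, 7, 29, 20, 15, 16),
                                            nc("5-butyldihydro-2(3H)-furanone"))
    ),
    C = list(
      "4-pentyl-pyridine" = pad(c(71, 26), nc("4-pentyl-pyridine")),
      "2-pentyl-thiophene" = pad(c(87, 9, 4), nc("2-pentyl-thiophene")),
      "2-pentylfuran" = pad(c(91, 9), nc("2-pentylfuran"))
    )
  )
}

#' Simulation configuration
#'
#' @param panel compound panel (named list of [compound_meta()]).
#' @param fractions nested list of true fractions per system and compound,
#'   see [default_true_fractions()].
#' @param n_replicates replicates per system (default 3, the usual GC-MS
#'   triplicate).
#' @param noise noise model, see [generate_cluster()].
#' @param cv proportional-noise CV (default 0.05).
#' @param total_signal expected summed window abundance (default 1e6).
#' @param seed master seed; every generated object derives its own stream
#'   from it, so no global random state is consumed.
#' @param correction convolve true fractions with natural abundance
#'   (default `TRUE`).
#' @return a list of class `camola_sim_config`.
#' @export
sim_config <- function(panel = default_compound_panel(),
                       fractions = default_true_fractions(panel),
                       n_replicates = 3, noise = "proportional", cv = 0.05,
                       total_signal = 1e6, seed = 1, correction = TRUE) {
  if (n_replicates < 1) stop_config("n_replicates must be >= 1")
  for (sys in names(fractions)) {
    for (cmp in names(fractions[[sys]])) {
      if (is.null(panel[[cmp]])) {
        stop_config("fractions refer to '%s' which is not in the panel", cmp)
      }
      f <- fractions[[sys]][[cmp]]
      if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
        stop_config("fractions for '%s' (system %s) are not a simplex", cmp, sys)
      }
    }
  }
  structure(
    list(panel = panel, fractions = fractions, n_replicates = n_replicates,
         noise = noise, cv = cv, total_signal = total_signal, seed = seed,
         correction = correction),
    class = "camola_sim_config"
  )
}

# Default ladder used by the simulator: C6..C30, monotone retention times
# approximating a 4 C/min temperature program on a 60 m column.
default_sim_ladder <- function() {
  n <- 6:30
  alkane_ladder(n, 2 + (n - 6) * 1.95)
}

# Retention time of a compound from its library RI by inverse van den Dool
# interpolation on the ladder.
rt_from_ri <- function(ri, ladder) {
  t <- ladder$retention_time
  n <- ladder$n_carbons
  x <- ri / 100
  i <- findInterval(x, n, rightmost.closed = TRUE)
  i[i >= length(n)] <- length(n) - 1L
  i[i < 1L] <- 1L
  t[i] + (x - n[i]) / (n[i + 1L] - n[i]) * (t[i + 1L] - t[i])
}

#' Generate a full synthetic experiment bundle
#'
#' Writes, under `dir`, everything the pipeline consumes plus the ground
#' truth: per system and replicate an MSP spectrum file and a molecular-ion
#' peak table, a compound metadata CSV, an alkane ladder CSV, and a truth
#' table `truth.csv` with columns
#' `compound,system,replicate,k,fraction_true,category_true`. Deterministic
#' under the config seed: each (system, replicate, compound) derives its
#' own sub-seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a manifest list of the written paths.
#' @export
generate_experiment <- function(config, dir) {
  stopifnot(inherits(config, "camola_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ladder <- default_sim_ladder()
  write_alkane_ladder(ladder, file.path(dir, "ladder.csv"))
  write_compound_meta(config$panel, file.path(dir, "metadata.csv"))
  truth <- list()
  paths <- list(ladder = file.path(dir, "ladder.csv"),
                metadata = file.path(dir, "metadata.csv"),
                spectra = character(0), peaks = character(0))
  sub_seed <- function(s, r, cidx) {
    (config$seed * 1009L + match(s, names(config$fractions)) * 101L +
       r * 11L + cidx) %% .Machine$integer.max
  }
  for (sys in names(config$fractions)) {
    cmps <- names(config$fractions[[sys]])
    for (rep in seq_len(config$n_replicates)) {
      spectra <- list()
      rows <- list()
      for (ci in seq_along(cmps)) {
        meta <- config$panel[[cmps[ci]]]
        f <- config$fractions[[sys]][[cmps[ci]]]
        cl <- generate_cluster(meta, f, total_signal = config$total_signal,
                               noise = config$noise, cv = config$cv,
                               seed = sub_seed(sys, rep, ci),
                               correction = config$correction)
        rt <- if (is.na(meta$library_ri)) NA_real_ else rt_from_ri(meta$library_ri, ladder)
        spectra[[ci]] <- ei_spectrum(meta$name, rt,
                                  data.frame(mz = cl$base_mz + 0:cl$n,
                                             abundance = cl$abundances))
        rows[[ci]] <- data.frame(compound_id = meta$name,
                                 mz = cl$base_mz + 0:cl$n,
                                 abundance = cl$abundances,
                                 stringsAsFactors = FALSE)
        summ <- summarize_labels(isotopomer_distribution(f))
        truth[[length(truth) + 1L]] <- data.frame(
          compound = meta$name, system = sys, replicate = rep,
          k = seq_along(f) - 1L, fraction_true = f,
          category_true = classify_origin(summ)$category,
          stringsAsFactors = FALSE
        )
      }
      msp <- file.path(dir, sprintf("system_%s_rep%d.msp", sys, rep))
      pk <- file.path(dir, sprintf("peaks_system_%s_rep%d.csv", sys, rep))
      write_msp(spectra, msp)
      utils::write.csv(do.call(rbind, rows), pk, row.names = FALSE)
      paths$spectra <- c(paths$spectra, msp)
      paths$peaks <- c(paths$peaks, pk)
    }
  }
  truth_df <- do.call(rbind, truth)
  paths$truth <- file.path(dir, "truth.csv")
  utils::write.csv(truth_df, paths$truth, row.names = FALSE)
  invisible(paths)
}
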