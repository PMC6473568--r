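#' Pipeline configuration
#'
#' Declarative description of one end-to-end run: input paths, mode flags,
#' and the output directory. Serializes round-trip to YAML via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param spectra path to the labeled-run MSP file.
#' @param metadata path to the compound metadata CSV.
#' @param ladder path to the alkane ladder CSV.
#' @param control_spectra optional MSP of the unlabeled-glucose control
#'   run; when given, the isotope-ratio report pairs control and labeled
#'   columns.
#' @param areas optional CSV (`compound,area`) for semi-quantitation.
#' @param internal_standard name of the internal-standard row in `areas`.
#' @param is_mass_ug internal-standard mass (ug).
#' @param sample_mass_g sample mass (g).
#' @param out_dir output directory for the report bundle.
#' @param correct_natural_abundance opt-in natural-abundance deconvolution
#'   (default `FALSE`: report raw ion ratios).
#' @param analyzed_ion_overrides named list mapping compound name to the
#'   number of analyzed ions (window width); e.g. `list("2-pentylfuran" = 2)`
#'   restricts that compound to M+0/M+1 with renormalization over the
#'   subset.
#' @param origin an [origin_thresholds()] object.
#' @param min_report_fraction threshold for listing a label count
#'   (percent, default 2).
#' @param ri_tolerance RI match tolerance (default 10).
#' @param log_level `"INFO"` or `"QUIET"`.
#' @return a list of class `camola_pipeline_config`.
#' @export
pipeline_config <- function(spectra, metadata, ladder,
                            control_spectra = NULL, areas = NULL,
                            internal_standard = "1,2-dichlorobenzene",
                            is_mass_ug = 0.4, sample_mass_g = 6.0,
                            out_dir = "camola_reports",
                            correct_natural_abundance = FALSE,
                            analyzed_ion_overrides = list(),
                            origin = origin_thresholds(),
                            min_report_fraction = 2,
                            ri_tolerance = 10,
                            log_level = c("INFO", "QUIET")) {
  log_level <- match.arg(log_level)
  cfg <- structure(
    list(spectra = spectra, metadata = metadata, ladder = ladder,
         control_spectra = control_spectra, areas = areas,
         internal_standard = internal_standard, is_mass_ug = is_mass_ug,
         sample_mass_g = sample_mass_g, out_dir = out_dir,
         correct_natural_abundance = correct_natural_abundance,
         analyzed_ion_overrides = analyzed_ion_overrides,
         origin = origin, min_report_fraction = min_report_fraction,
         ri_tolerance = ri_tolerance, log_level = log_level),
    class = "camola_pipeline_config"
  )
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `camola_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  thr <- y$origin
  y$origin <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(thr)) cfg$origin <- do.call(origin_thresholds, thr)
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `camola_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$origin <- unclass(config$origin)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "INFO")) {
    message(sprintf(paste0("[camola] ", fmt), ...))
  }
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: read inputs; retention-index assignment and library matching;
#' optional internal-standard quantitation with OAVs; molecular-ion cluster
#' extraction; isotope-ratio normalization (or natural-abundance
#' deconvolution when enabled); label summaries; origin calls. Emits CSV
#' reports (`ri_report.csv`, `quant_report.csv`, `isotope_report.csv`,
#' `proportion_report.csv`, `origin_report.csv`) plus a JSON run manifest.
#' Any stage error aborts the run, removes partial outputs, and names the
#' stage and compound.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the report data frames and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "camola_pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "read-inputs"
  result <- tryCatch({
    metas <- read_compound_meta(config$metadata)
    ladder <- read_alkane_ladder(config$ladder)
    spectra <- read_msp(config$spectra)
    control <- if (!is.null(config$control_spectra)) read_msp(config$control_spectra)

    stage <- "retention-index"
    ri_rows <- lapply(spectra, function(sp) {
      ri <- if (is.na(sp$retention_time)) NA_real_ else
        kovats_ri(sp$retention_time, ladder)
      hits <- if (is.na(ri)) data.frame() else
        match_ri(ri, metas, tol = config$ri_tolerance)
      data.frame(compound = sp$compound_id, rt = sp$retention_time, ri = ri,
                 best_match = if (nrow(hits)) hits$name[1] else NA_character_,
                 delta_ri = if (nrow(hits)) hits$delta_ri[1] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    ri_report <- do.call(rbind, ri_rows)

    quant_report <- NULL
    if (!is.null(config$areas)) {
      stage <- "quantitation"
      areas <- utils::read.csv(config$areas, stringsAsFactors = FALSE)
      thr <- vapply(metas, `[[`, numeric(1), "odor_threshold")
      quant_report <- quantify_batch(areas, config$internal_standard,
                                     config$is_mass_ug, config$sample_mass_g,
                                     thresholds = thr)
    }

    stage <- "isotopologue"
    analyze_run <- function(run_spectra) {
      res <- list()
      for (sp in run_spectra) {
        meta <- metas[[sp$compound_id]]
        if (is.null(meta)) next
        ovr <- config$analyzed_ion_overrides[[meta$name]]
        n <- if (is.null(ovr)) NULL else as.integer(ovr) - 1L
        cl <- extract_cluster(sp, meta, n = n)
        dist <- if (config$correct_natural_abundance) {
          deconvolve(cl, build_correction_matrix(meta, n = cl$n))
        } else {
          normalize_cluster(cl)
        }
        res[[meta$name]] <- list(cluster = cl, dist = dist)
      }
      res
    }
    labeled <- analyze_run(spectra)
    control_res <- if (!is.null(control)) analyze_run(control)

    iso_rows <- lapply(names(labeled), function(nm) {
      cl <- labeled[[nm]]$cluster
      lab_pct <- 100 * as.numeric(labeled[[nm]]$dist)
      ctl_pct <- if (!is.null(control_res) && !is.null(control_res[[nm]])) {
        v <- 100 * as.numeric(control_res[[nm]]$dist)
        length(v) <- length(lab_pct)
        v
      } else rep(NA_real_, length(lab_pct))
      data.frame(compound = nm, mz = cl$base_mz + 0:cl$n,
                 control = ctl_pct, labeled = lab_pct,
                 stringsAsFactors = FALSE)
    })
    iso_report <- do.call(rbind, iso_rows)

    stage <- "label-summary"
    prop_rows <- lapply(names(labeled), function(nm) {
      summ <- summarize_labels(labeled[[nm]]$dist,
                               min_report_fraction = config$min_report_fraction)
      data.frame(
        compound = nm,
        m_plus = labeled[[nm]]$cluster$base_mz,
        pct_unlabeled = round_half_up(summ$pct_unlabeled, 1),
        pct_labeled = paste(round_half_up(summ$pct_labeled_by_k, 1), collapse = ";"),
        labeled_carbon_numbers = paste(summ$labeled_carbon_numbers, collapse = ";"),
        stringsAsFactors = FALSE
      )
    })
    prop_report <- do.call(rbind, prop_rows)

    stage <- "origin-call"
    origin_rows <- lapply(names(labeled), function(nm) {
      summ <- summarize_labels(labeled[[nm]]$dist,
                               min_report_fraction = config$min_report_fraction)
      call <- classify_origin(summ, config$origin)
      data.frame(compound = nm, category = call$category,
                 pct_unlabeled = round_half_up(call$pct_unlabeled, 1),
                 pct_fully_labeled = round_half_up(call$pct_fully_labeled, 1),
                 stringsAsFactors = FALSE)
    })
    origin_report <- do.call(rbind, origin_rows)

    stage <- "write-reports"
    paths <- list(
      ri = emit(ri_report, "ri_report.csv"),
      isotope = {
        p <- file.path(out_dir, "isotope_report.csv")
        iso_out <- iso_report
        write_isotope_table(
          data.frame(compound = iso_out$compound, mz = iso_out$mz,
                     control = ifelse(is.na(iso_out$control), 0, iso_out$control),
                     labeled = iso_out$labeled),
          p)
        written <- c(written, p)
        p
      },
      proportion = emit(prop_report, "proportion_report.csv"),
      origin = emit(origin_report, "origin_report.csv")
    )
    if (!is.null(quant_report)) paths$quant <- emit(quant_report, "quant_report.csv")

    manifest <- list(
      package = "camola",
      version = as.character(utils::packageVersion("camola")),
      r_version = R.version.string,
      config = unclass(write_safe_config(config)),
      compounds = names(labeled),
      reports = unname(unlist(paths))
    )
    manifest_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, manifest_path)
    pipe_log(config, "wrote %d report files to %s", length(written), out_dir)
    list(ri = ri_report, quant = quant_report, isotope = iso_report,
         proportion = prop_report, origin = origin_report, paths = paths,
         manifest = manifest_path)
  }, error = function(e) {
    unlink(written)
    if (inherits(e, "camola_error")) {
      stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", stage,
                                  conditionMessage(e)),
                          class = class(e)))
    }
    stop_data("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# Config serialized into the manifest (drop function-like fields, keep flags).
write_safe_config <- function(config) {
  y <- unclass(config)
  y$origin <- unclass(config$origin)
  y[!vapply(y, is.null, logical(1))]
}
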