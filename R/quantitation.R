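#' Internal-standard semi-quantitation
#'
#' Estimates the concentration of a compound from the ratio of its peak
#' area to that of the internal standard:
#' `W_i = f' * A_i * m_s / (A_s * m)`,
#' with `A_i` the analyte peak area, `A_s` the internal-standard peak area,
#' `m_s` the internal-standard mass in micrograms, `m` the sample mass in
#' grams, and `f'` the relative response factor (1 by default, i.e. unit
#' response and full recovery assumed). The result is in ug/g.
#'
#' @param area analyte peak area(s), arbitrary units >= 0.
#' @param is_area internal-standard peak area (> 0), same units.
#' @param is_mass_ug internal-standard mass in ug (>= 0).
#' @param sample_mass_g sample mass in g (> 0).
#' @param response_factor relative response factor `f'` (> 0, default 1).
#' @return concentration(s) in ug/g.
#' @export
#' @examples
#' semi_quant(2423, 1000, 3.0, 6.0)  # 1.2115 ug/g
semi_quant <- function(area, is_area, is_mass_ug, sample_mass_g,
                       response_factor = 1) {
  if (any(is_area <= 0)) stop_data("internal-standard area must be positive")
  if (any(sample_mass_g <= 0)) stop_data("sample mass must be positive")
  if (any(is_mass_ug < 0)) stop_data("internal-standard mass must be >= 0")
  if (any(response_factor <= 0)) stop_data("response factor must be positive")
  if (any(area < 0)) stop_data("peak area must be >= 0")
  response_factor * area * is_mass_ug / (is_area * sample_mass_g)
}

#' Odor activity value
#'
#' OAV = concentration / odor detection threshold, both in ug/g; values
#' above 1 suggest the compound is perceptible in the matrix. Reported
#' rounded half-up to one decimal (the precision used for published OAVs);
#' set `digits = NA` for the raw ratio. A missing threshold yields `NA`
#' (absent), never zero.
#'
#' @param concentration concentration(s) in ug/g.
#' @param threshold odor detection threshold(s) in ug/g (> 0), or `NA`.
#' @param digits decimals for the report value (default 1; `NA` = no
#'   rounding).
#' @return odor activity value(s).
#' @export
#' @examples
#' odor_activity(1.211, 0.006)  # 201.8
odor_activity <- function(concentration, threshold, digits = 1) {
  if (any(threshold <= 0, na.rm = TRUE)) stop_data("odor threshold must be positive")
  oav <- concentration / threshold
  if (!is.na(digits)) oav <- round_half_up(oav, digits)
  oav
}

#' Quantify a batch of compounds against the internal standard
#'
#' @param areas data frame with columns `compound` and `area`.
#' @param internal_standard name of the internal-standard row in `areas`.
#' @param is_mass_ug internal-standard mass (ug).
#' @param sample_mass_g sample mass (g).
#' @param thresholds optional named vector of odor thresholds (ug/g) keyed
#'   by compound name.
#' @param response_factor relative response factor (default 1).
#' @return data frame `compound`, `area`, `conc_ug_g`, `oav` (OAV is `NA`
#'   where no threshold is known).
#' @export
quantify_batch <- function(areas, internal_standard, is_mass_ug, sample_mass_g,
                           thresholds = NULL, response_factor = 1) {
  areas <- as.data.frame(areas)
  if (!all(c("compound", "area") %in% names(areas))) {
    stop_data("areas must have columns 'compound' and 'area'")
  }
  is_row <- areas$compound == internal_standard
  if (!any(is_row)) stop_data("internal standard '%s' not found in areas", internal_standard)
  is_area <- areas$area[which(is_row)[1]]
  out <- areas[!is_row, c("compound", "area"), drop = FALSE]
  out$conc_ug_g <- semi_quant(out$area, is_area, is_mass_ug, sample_mass_g,
                              response_factor)
  thr <- if (is.null(thresholds)) rep(NA_real_, nrow(out)) else
    unname(thresholds[out$compound])
  out$oav <- ifelse(is.na(thr), NA_real_, odor_activity(out$conc_ug_g, thr))
  rownames(out) <- NULL
  out
}
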