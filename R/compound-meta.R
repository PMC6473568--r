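#' Compound metadata
#'
#' Describes one analyte: name, elemental formula (C/H/N/O/S), nominal
#' molecular mass, carbon count, and optionally an odor threshold and a
#' library retention index. The nominal mass is computed from the formula
#' using integer isotope masses (C 12, H 1, N 14, O 16, S 32); when a mass
#' is supplied it must agree with the formula within 1 u.
#'
#' @param name compound name.
#' @param formula elemental formula, either a string such as `"C9H14O"` or a
#'   named integer vector `c(C = 9, H = 14, O = 1)`. Only C, H, N, O and S
#'   are accepted (the element inventory of the volatiles analysed here).
#' @param odor_threshold odor detection threshold in ug/g (optional).
#' @param library_ri reference retention index on a DB-5-type column
#'   (optional).
#' @param nominal_mass integer molecular-ion mass; computed from the
#'   formula when omitted.
#' @return an object of class `camola_compound`.
#' @export
#' @examples
#' compound_meta("2-pentylfuran", "C9H14O", odor_threshold = 0.006,
#'               library_ri = 985)
compound_meta <- function(name, formula, odor_threshold = NA_real_,
                          library_ri = NA_real_, nominal_mass = NULL) {
  counts <- parse_formula(formula)
  mass <- nominal_mass_from_counts(counts)
  if (!is.null(nominal_mass)) {
    if (abs(nominal_mass - mass) > 1) {
      stop_data("nominal mass %d inconsistent with formula (expected %d) for '%s'",
                as.integer(nominal_mass), mass, name)
    }
    mass <- as.integer(nominal_mass)
  }
  if (counts[["C"]] < 1L) stop_data("'%s': formula must contain carbon", name)
  if (!is.na(odor_threshold) && odor_threshold <= 0) {
    stop_data("'%s': odor threshold must be positive", name)
  }
  structure(
    list(
      name = name,
      formula = counts,
      nominal_mass = mass,
      carbon_count = counts[["C"]],
      odor_threshold = odor_threshold,
      library_ri = library_ri
    ),
    class = "camola_compound"
  )
}

#' @export
print.camola_compound <- function(x, ...) {
  fml <- paste0(names(x$formula)[x$formula > 0],
                ifelse(x$formula[x$formula > 0] > 1, x$formula[x$formula > 0], ""),
                collapse = "")
  cat(sprintf("<camola_compound> %s (%s, M+ %d, %d C)\n",
              x$name, fml, x$nominal_mass, x$carbon_count))
  invisible(x)
}

parse_formula <- function(formula) {
  elements <- c("C", "H", "N", "O", "S")
  counts <- stats::setNames(integer(5L), elements)
  if (is.numeric(formula)) {
    bad <- setdiff(names(formula), elements)
    if (length(bad)) stop_data("unsupported element(s): %s", paste(bad, collapse = ", "))
    counts[names(formula)] <- as.integer(formula)
    return(counts)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks) || paste(toks, collapse = "") != formula) {
    stop_data("cannot parse formula '%s'", formula)
  }
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% elements) stop_data("unsupported element '%s' in formula '%s'", el, formula)
    counts[el] <- counts[el] + n
  }
  counts
}

nominal_mass_from_counts <- function(counts) {
  masses <- c(C = 12L, H = 1L, N = 14L, O = 16L, S = 32L)
  as.integer(sum(counts * masses[names(counts)]))
}

#' Read a compound metadata table
#'
#' Expects a CSV with columns `name`, `formula` and optionally
#' `odor_threshold` (ug/g) and `library_ri`.
#'
#' @param path path to the CSV file.
#' @return a named list of [compound_meta()] objects.
#' @export
read_compound_meta <- function(path) {
  if (!file.exists(path)) stop_data("metadata file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula")
  if (!all(need %in% names(df))) {
    stop_data("metadata must have columns: %s", paste(need, collapse = ", "))
  }
  if (!"odor_threshold" %in% names(df)) df$odor_threshold <- NA_real_
  if (!"library_ri" %in% names(df)) df$library_ri <- NA_real_
  metas <- lapply(seq_len(nrow(df)), function(i) {
    compound_meta(df$name[i], df$formula[i],
                  odor_threshold = as.numeric(df$odor_threshold[i]),
                  library_ri = as.numeric(df$library_ri[i]))
  })
  stats::setNames(metas, df$name)
}

#' Write a compound metadata table
#'
#' @param metas a list of [compound_meta()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_meta <- function(metas, path) {
  df <- do.call(rbind, lapply(metas, function(m) {
    fml <- paste0(names(m$formula)[m$formula > 0],
                  ifelse(m$formula[m$formula > 0] > 1, m$formula[m$formula > 0], ""),
                  collapse = "")
    data.frame(name = m$name, formula = fml, nominal_mass = m$nominal_mass,
               carbon_count = m$carbon_count, odor_threshold = m$odor_threshold,
               library_ri = m$library_ri, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
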