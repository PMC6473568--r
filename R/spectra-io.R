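#' EI mass spectrum at unit-mass resolution
#'
#' A peak list (nominal m/z, abundance) for one compound with its retention
#' time. Fractional m/z values are binned to the nearest integer by summing
#' abundances; the acquisition window is 40-400 u and peaks outside it are
#' kept with a warning.
#'
#' @param compound_id compound identifier.
#' @param retention_time retention time in minutes (>= 0), or `NA`.
#' @param peaks a two-column data frame or matrix with columns `mz` and
#'   `abundance` (arbitrary non-negative units).
#' @return an object of class `camola_spectrum` with binned, mz-sorted peaks.
#' @export
#' @examples
#' ei_spectrum("x", 12.3, data.frame(mz = c(138.2, 138.4), abundance = c(500, 412)))
ei_spectrum <- function(compound_id, retention_time, peaks) {
  peaks <- as.data.frame(peaks)
  if (!all(c("mz", "abundance") %in% names(peaks))) {
    stop_data("peaks must have columns 'mz' and 'abundance'")
  }
  if (any(!is.finite(peaks$mz)) || any(!is.finite(peaks$abundance))) {
    stop_data("spectrum '%s': non-numeric peak entries", compound_id)
  }
  if (any(peaks$abundance < 0)) {
    stop_data("spectrum '%s': negative abundance", compound_id)
  }
  if (!is.na(retention_time) && retention_time < 0) {
    stop_data("spectrum '%s': negative retention time", compound_id)
  }
  peaks <- bin_nominal(peaks)
  if (nrow(peaks) && any(peaks$mz < 40 | peaks$mz > 400)) {
    warning(sprintf("spectrum '%s': peak(s) outside the 40-400 u mass range (kept)",
                    compound_id))
  }
  structure(
    list(compound_id = compound_id, retention_time = retention_time, peaks = peaks),
    class = "camola_spectrum"
  )
}

# Sum abundances within each unit-mass bin; sort strictly ascending.
bin_nominal <- function(peaks) {
  if (!nrow(peaks)) {
    return(data.frame(mz = integer(0), abundance = numeric(0)))
  }
  nominal <- as.integer(floor(peaks$mz + 0.5))
  ab <- tapply(peaks$abundance, nominal, sum)
  data.frame(mz = as.integer(names(ab)), abundance = as.numeric(ab),
             row.names = NULL)
}

#' @export
print.camola_spectrum <- function(x, ...) {
  cat(sprintf("<camola_spectrum> %s  rt %.2f min  %d peaks\n",
              x$compound_id, x$retention_time, nrow(x$peaks)))
  invisible(x)
}

#' Read an MSP (NIST text) spectral library
#'
#' Records are separated by blank lines and carry `Name:` and `Num Peaks:`
#' headers followed by mz/intensity pairs. Pairs may be whitespace-,
#' comma- or semicolon-separated, several per line. An optional `RT:` (or
#' `Retention_time:`) header is read as minutes. Peaks are binned to
#' nominal integer m/z on input.
#'
#' @param path path to the MSP file.
#' @return a list of [ei_spectrum()] objects, in file order.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop_data("MSP file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  # Split into records at blank lines
  grp <- cumsum(lines == "")
  keep <- lines != ""
  if (!any(keep)) return(list())
  recs <- split(lines[keep], grp[keep])
  out <- lapply(recs, parse_msp_record)
  names(out) <- NULL
  out
}

parse_msp_record <- function(rec) {
  kv <- grepl("^[A-Za-z][A-Za-z _]*:", rec)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), rec, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^[^:]*:", "", hit[1]))
  }
  name <- get_field("Name")
  if (is.na(name)) name <- "(unnamed)"
  np_line <- grep("^Num ?Peaks:", rec, ignore.case = TRUE)
  if (!length(np_line)) {
    stop_data("MSP record '%s': missing 'Num Peaks' header", name)
  }
  n_peaks <- suppressWarnings(as.integer(get_field("Num ?Peaks")))
  if (is.na(n_peaks)) stop_data("MSP record '%s': unreadable 'Num Peaks'", name)
  rt <- suppressWarnings(as.numeric(get_field("(RT|Retention_?time)")))
  peak_lines <- rec[seq_along(rec) > np_line[1]]
  peak_lines <- peak_lines[!grepl("^[A-Za-z][A-Za-z _]*:", peak_lines)]
  toks <- unlist(strsplit(paste(peak_lines, collapse = " "), "[;,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals)) || length(vals) %% 2L != 0L) {
    stop_data("MSP record '%s': malformed peak list", name)
  }
  if (length(vals) / 2L != n_peaks) {
    stop_data("MSP record '%s': Num Peaks is %d but %d pairs found",
              name, n_peaks, length(vals) / 2L)
  }
  mz <- vals[seq(1L, length(vals), by = 2L)]
  ab <- vals[seq(2L, length(vals), by = 2L)]
  ei_spectrum(name, rt, data.frame(mz = mz, abundance = ab))
}

#' Write spectra to an MSP file
#'
#' @param spectra a list of [ei_spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(sprintf("Name: %s", sp$compound_id), con)
    if (!is.na(sp$retention_time)) {
      writeLines(sprintf("RT: %.4f", sp$retention_time), con)
    }
    writeLines(sprintf("Num Peaks: %d", nrow(sp$peaks)), con)
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%d %.12g", sp$peaks$mz, sp$peaks$abundance), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a molecular-ion peak table
#'
#' A CSV with columns `compound_id`, `mz`, `abundance` holding the raw
#' molecular-ion region of each compound. Rows are grouped by compound
#' (independently of row order) into contiguous clusters from the lowest to
#' the highest observed m/z; unobserved masses inside the window get
#' abundance 0.
#'
#' @param path path to the CSV file.
#' @return a named list of [isotope_cluster()] objects.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop_data("peak table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("compound_id", "mz", "abundance")
  if (!all(need %in% names(df))) {
    stop_data("peak table must have columns: %s", paste(need, collapse = ", "))
  }
  mz <- suppressWarnings(as.numeric(df$mz))
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(is.na(mz) | is.na(ab))
  if (length(bad)) {
    stop_data("peak table row %d: non-numeric mz/abundance ('%s', '%s')",
              bad[1], df$mz[bad[1]], df$abundance[bad[1]])
  }
  if (any(ab < 0)) {
    stop_data("peak table row %d: negative abundance (corrupted export?)",
              which(ab < 0)[1])
  }
  ids <- unique(df$compound_id)
  out <- lapply(ids, function(id) {
    sel <- df$compound_id == id
    m <- as.integer(floor(mz[sel] + 0.5))
    a <- ab[sel]
    base <- min(m)
    abund <- numeric(max(m) - base + 1L)
    for (i in seq_along(m)) {
      abund[m[i] - base + 1L] <- abund[m[i] - base + 1L] + a[i]
    }
    isotope_cluster(id, base, abund)
  })
  stats::setNames(out, ids)
}

#' Write an isotope-ratio report table
#'
#' Emits the paired control/labeled percentage table for the molecular-ion
#' region of each compound (the shape of the published isotope-ratio
#' tables): columns `compound`, `mz`, `control`, `labeled`, percentages
#' rounded half-up to one decimal.
#'
#' @param rows data frame with columns `compound`, `mz`, `control`,
#'   `labeled` (percentages in \[0, 100\]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  need <- c("compound", "mz", "control", "labeled")
  if (nrow(rows) && !all(need %in% names(rows))) {
    stop_data("isotope table needs columns: %s", paste(need, collapse = ", "))
  }
  if (!nrow(rows)) {
    rows <- data.frame(compound = character(0), mz = integer(0),
                       control = numeric(0), labeled = numeric(0))
  }
  pc <- c(rows$control, rows$labeled)
  if (length(pc) && (any(pc < 0, na.rm = TRUE) || any(pc > 100, na.rm = TRUE))) {
    stop_data("isotope table percentages must lie in [0, 100]")
  }
  out <- data.frame(
    compound = rows$compound,
    mz = rows$mz,
    control = sprintf("%.1f", round_half_up(rows$control, 1)),
    labeled = sprintf("%.1f", round_half_up(rows$labeled, 1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' n-alkane retention ladder
#'
#' The C6-C30 straight-chain alkane series used to anchor retention
#' indices. Carbon numbers and retention times must both be strictly
#' increasing.
#'
#' @param n_carbons integer alkane carbon numbers (within 6..30).
#' @param retention_time retention times in minutes.
#' @return an object of class `camola_ladder` (a data frame).
#' @export
alkane_ladder <- function(n_carbons, retention_time) {
  n_carbons <- as.integer(n_carbons)
  if (length(n_carbons) != length(retention_time)) {
    stop_data("ladder: n_carbons and retention_time lengths differ")
  }
  if (length(n_carbons) < 2L) stop_data("ladder needs at least two alkanes")
  if (any(n_carbons < 6L) || any(n_carbons > 30L)) {
    stop_data("ladder alkanes must lie in C6..C30")
  }
  if (any(diff(n_carbons) <= 0L)) stop_data("ladder carbon numbers must strictly increase")
  if (any(diff(retention_time) <= 0)) stop_data("ladder retention times must strictly increase")
  structure(
    data.frame(n_carbons = n_carbons, retention_time = as.numeric(retention_time)),
    class = c("camola_ladder", "data.frame")
  )
}

#' Read an alkane ladder CSV
#'
#' Columns `n_carbons` (or `n`) and `retention_time` (or `rt`).
#'
#' @param path path to the CSV file.
#' @return a [alkane_ladder()] object.
#' @export
read_alkane_ladder <- function(path) {
  if (!file.exists(path)) stop_data("ladder file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  ncol_ <- if ("n_carbons" %in% nm) "n_carbons" else if ("n" %in% nm) "n" else
    stop_data("ladder needs an 'n_carbons' (or 'n') column")
  rcol <- if ("retention_time" %in% nm) "retention_time" else if ("rt" %in% nm) "rt" else
    stop_data("ladder needs a 'retention_time' (or 'rt') column")
  alkane_ladder(df[[ncol_]], df[[rcol]])
}

#' Write an alkane ladder CSV
#'
#' @param ladder a [alkane_ladder()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_alkane_ladder <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE)
  invisible(path)
}
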