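#' Linear (van den Dool) retention index
#'
#' Temperature-programmed retention index against the alkane ladder:
#' `RI = 100 * (n + (rt - t_n) / (t_(n+1) - t_n))` with `n`, `n+1` the
#' bracketing alkanes. At a ladder node the index is exactly `100 * n`;
#' between nodes it interpolates linearly (also across a gap in the
#' ladder, scaled by the carbon-number difference). No extrapolation:
#' retention times outside the ladder raise an error.
#'
#' @param rt retention time(s) in minutes.
#' @param ladder a [alkane_ladder()] object.
#' @return numeric vector of retention indices.
#' @export
#' @examples
#' lad <- alkane_ladder(6:12, c(2, 4.5, 7.5, 10, 12, 14.5, 17))
#' kovats_ri(11.5, lad)  # 975
kovats_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "camola_ladder"))
  t <- ladder$retention_time
  n <- ladder$n_carbons
  if (any(rt < t[1] - 1e-12) || any(rt > t[length(t)] + 1e-12)) {
    stop_data("retention time outside the ladder range [%.3f, %.3f] min",
              t[1], t[length(t)])
  }
  i <- findInterval(rt, t, rightmost.closed = TRUE)
  i[i >= length(t)] <- length(t) - 1L
  i[i < 1L] <- 1L
  100 * (n[i] + (rt - t[i]) / (t[i + 1L] - t[i]) * (n[i + 1L] - n[i]))
}

#' Match a retention index against a compound library
#'
#' Returns library compounds whose reference RI lies within `tol` units of
#' the observed index, ranked by absolute difference; ties are broken
#' alphabetically by name. An empty result is allowed.
#'
#' @param ri observed retention index.
#' @param library a list of [compound_meta()] objects (or a data frame with
#'   columns `name` and `library_ri`).
#' @param tol match tolerance in RI units (> 0 unless exactly 0 is wanted;
#'   default 10, a typical inter-laboratory spread on DB-5 phases).
#' @return data frame with columns `name`, `library_ri`, `delta_ri`.
#' @export
match_ri <- function(ri, library, tol = 10) {
  if (tol < 0) stop_config("match tolerance must be >= 0")
  if (is.data.frame(library)) {
    df <- library[, c("name", "library_ri")]
  } else {
    df <- data.frame(
      name = vapply(library, `[[`, character(1), "name"),
      library_ri = vapply(library, `[[`, numeric(1), "library_ri"),
      stringsAsFactors = FALSE
    )
  }
  df <- df[!is.na(df$library_ri), , drop = FALSE]
  df$delta_ri <- abs(df$library_ri - ri)
  df <- df[df$delta_ri <= tol, , drop = FALSE]
  df <- df[order(df$delta_ri, df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}
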