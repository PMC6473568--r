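# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report tables print percentages rounded half-up (0.05 -> 0.1), unlike
#' base [round()] which rounds half to even. A small epsilon guards against
#' values such as 91.15 being represented as 91.14999... in binary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the precision of the
#'   report tables).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.04999, 201.8333))
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Condition constructors: the CLI maps these classes to exit codes
# (config -> 2, data -> 3, numeric -> 4).
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("camola_config_error", "camola_error")))
}
stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("camola_data_error", "camola_error")))
}
stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("camola_numeric_error", "camola_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# Discrete convolution of two non-negative mass-shift polynomials
# (coefficient vectors indexed from shift 0).
conv_poly <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# n-fold convolution power of a mass-shift polynomial.
conv_pow <- function(a, n) {
  stopifnot(n >= 0)
  out <- 1
  for (i in seq_len(n)) out <- conv_poly(out, a)
  out
}
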