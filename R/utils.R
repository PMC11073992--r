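#' Z-score a numeric vector
#'
#' Centres and scales by the realized sample mean and standard deviation.
#' A constant vector (sd of zero, or a single value) is returned as all
#' zeros rather than NaN, so degenerate predictors drop out of model fits
#' instead of poisoning them.
#'
#' @param x numeric vector; NAs are ignored for the moments and preserved
#'   in the output.
#' @return numeric vector of the same length.
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - m) / s
}

# internal: validate a participants x features numeric matrix
check_matrix <- function(values, what = "values") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
  values
}

# internal: derive a replicate seed from a base seed, kept inside 32-bit
# integer range
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647L)
}
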