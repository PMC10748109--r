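#' Round half away from zero
#'
#' Deterministic half-up rounding used for the printed summary tables, where
#' e.g. 64.5 must round to 65 (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by one ulp so values like 0.285 stored as 0.28499999... still round up
  sign(x) * floor(abs(x) * p + 0.5 + .Machine$double.eps * abs(x) * p) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}

# number of samples spanned by a duration in minutes on a grid of interval_s
# seconds; errors if it spans fewer than `min_samples`
window_samples <- function(window_min, interval_s, min_samples = 2L) {
  assert_scalar_number(window_min, "window_min", positive = TRUE)
  n <- as.integer(round(window_min * 60 / interval_s))
  if (n < min_samples)
    stopf("window of %g min spans %d sample(s) at interval %g s; need >= %d",
          window_min, n, interval_s, min_samples)
  n
}
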