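#' Round half away from zero
#'
#' Reporting-layer rounding used for contribution percentages: exact halves
#' round away from zero (so 24.825 -> 24.83), unlike [base::round()]'s
#' round-half-even. Applied only when formatting results, never inside the
#' model arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

# internal: days in a calendar year
days_in_year <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
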