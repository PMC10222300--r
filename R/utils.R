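#' Round half away from zero
#'
#' Reporting-precision rounding used throughout the bench arithmetic:
#' exact halves round away from zero (105.07 -> 105.1, 78.85 -> 78.9),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, half away from zero.
#' @export
#' @examples
#' roundHalfUp(105.07)  # 105.1
#' roundHalfUp(0.25, 1) # 0.3
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## scalar type checks used by validity methods
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
isScalarCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

## label equality treating NA as a label of its own
sameLabel <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
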