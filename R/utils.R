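#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can match on condition class.
abort2 <- function(message, class) {
  stop(errorCondition(message, class = c(class, "stemflowS_error")))
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up for positive input), as opposed
#' to the round-half-even rule of [base::round()]. Used for the delay rule,
#' where `12 / (12/7) = 7` must stay 7 and e.g. `12 / (8/3) = 4.5` becomes 5.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
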