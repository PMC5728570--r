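# Small shared helpers.

#' Round half away from zero
#'
#' Table-style rounding (0.5 always rounds away from zero), used when
#' formatting report percentages so printed cells match conventional
#' summary tables rather than R's round-half-even default.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
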