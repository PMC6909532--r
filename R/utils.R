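#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for the tabulated PAFs and risk ratios this package reports (base R's
#' `round()` rounds half to even).  A small epsilon guards against values such
#' as 0.2315 being stored as 0.23149999... in binary.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @examples
#' round_half_up(0.2225, 3)  # 0.223, where round() gives 0.222
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix for data-validation failures
stop_data <- function(...) stop(..., call. = FALSE)
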