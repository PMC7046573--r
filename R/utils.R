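#' Round half away from zero
#'
#' Commercial rounding as used in published incidence tables: ties go away
#' from zero (`round_half_away(0.5) == 1`), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(235.78)   # 236
#' round_half_away(1.55, 1)  # 1.6
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() wrapper keeping call noise out of user-facing errors
abort_input <- function(...) stop(..., call. = FALSE)
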