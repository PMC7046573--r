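#' Age-band schemes
#'
#' Age bands are closed-open intervals `[age_lo, age_hi)` in completed years,
#' with an open-ended terminal band (`age_hi = Inf`, printed as e.g. "95+").
#' Together the bands of a scheme partition `[min_age, Inf)` without gaps or
#' overlap.
#'
#' `age_bands()` builds a scheme from the lower bound of every band;
#' `hip_age_bands()` is the 5-year scheme 40-44 ... 90-94, 95+ used for hip
#' fracture tabulation, and `decade_age_bands()` the 10-year scheme
#' 40-49 ... 80-89, 90+ used for forearm and humerus.
#'
#' @param lowers Integer vector of band lower bounds, strictly increasing.
#'   The last entry opens the terminal band.
#' @return A tibble with columns `age_lo`, `age_hi` (Inf for the terminal
#'   band) and `band` (printed label such as "40-44" or "95+").
#' @examples
#' hip_age_bands()
#' age_bands(c(50, 60, 70))
#' @export
age_bands <- function(lowers) {
  lowers <- as.integer(lowers)
  if (length(lowers) < 1L || is.unsorted(lowers, strictly = TRUE)) {
    abort_input("`lowers` must be a strictly increasing integer vector")
  }
  hi <- c(lowers[-1], Inf)
  tibble::tibble(
    age_lo = as.numeric(lowers),
    age_hi = hi,
    band = ifelse(is.finite(hi),
      paste0(lowers, "-", hi - 1),
      paste0(lowers, "+")
    )
  )
}

#' @rdname age_bands
#' @export
hip_age_bands <- function() age_bands(seq(40L, 95L, by = 5L))

#' @rdname age_bands
#' @export
decade_age_bands <- function() age_bands(seq(40L, 90L, by = 10L))

#' Assign ages to the bands of a scheme
#'
#' @param age Numeric vector of ages in completed years.
#' @param bands An age-band scheme from [age_bands()].
#' @return Character vector of band labels (`NA` for ages below the first
#'   band).
#' @examples
#' assign_age_band(c(44, 45, 97), hip_age_bands())
#' @export
assign_age_band <- function(age, bands) {
  idx <- findInterval(age, bands$age_lo)
  out <- rep(NA_character_, length(age))
  out[idx > 0] <- bands$band[idx[idx > 0]]
  out
}

# TRUE when every band of `coarse` is the exact union of consecutive bands
# of `fine` (same overall support)
bands_nest_in <- function(fine, coarse) {
  all(coarse$age_lo %in% fine$age_lo) &&
    min(fine$age_lo) == min(coarse$age_lo)
}
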