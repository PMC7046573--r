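#' Bundled catchment surveillance tables
#'
#' Machine-readable copies of the regional surveillance results the
#' package's defaults are calibrated to: a three-year (2015-2017) hip
#' fracture survey and a two-year (2015-2016) forearm/humerus survey of a
#' catchment area of about 165,000 people in Kazakhstan, together with the
#' published predicted-versus-observed comparison against Malmo-derived
#' rates and the headline constants of the survey. These tables drive the
#' package's validation suite and the worked examples; they contain no
#' person-level data.
#'
#' @return A list with components:
#' \describe{
#'   \item{hip_incidence}{Tibble `sex`, `age_lo`, `age_hi`, `site`,
#'     `person_years` (three-year person-years: the annual stratum
#'     populations summed over 2015-2017) and `events` (unadjusted case
#'     counts), on 5-year bands 40-44 ... 95+.}
#'   \item{appendicular_counts}{Tibble of forearm and humerus case counts
#'     (2015-2016) on 10-year bands 40-49 ... 90+.}
#'   \item{appendicular_totals}{Published 40+ totals per site and sex with
#'     printed rates and 95% intervals.}
#'   \item{predicted_observed}{Published predicted (Malmo-ratio) vs
#'     observed rates per 100,000 for ages 50-89, with the observed 95%
#'     interval and the published significance flag.}
#'   \item{constants}{Named list of headline survey constants: total case
#'     counts by site, care-pathway counts (348 hip cases, 82 refusals,
#'     266 admitted, 200 surgical), the prospective-phase uplift inputs
#'     (65 + 65 retrospective and 84 prospective annual female cases, 19
#'     additional), the adjusted 40+ event counts implied by the published
#'     adjusted rates, and the published 40+ rates and intervals.}
#' }
#' @export
fixture_tables <- function() {
  hip <- tibble::tibble(
    sex = rep(c("male", "female"), each = 12),
    age_lo = rep(c(seq(40, 90, 5), 95), 2),
    age_hi = rep(c(seq(45, 95, 5), Inf), 2),
    site = "hip",
    person_years = c(
      15668, 14234, 13691, 11371, 8377, 6387,
      3279, 2665, 1323, 593, 211, 150,
      19142, 17874, 17099, 15231, 11984, 10058,
      5169, 5665, 2833, 1360, 357, 108
    ),
    events = c(
      10, 9, 10, 18, 18, 23, 8, 13, 10, 12, 3, 0,
      5, 4, 6, 14, 16, 25, 21, 44, 38, 31, 10, 0
    )
  )
  appendicular <- tibble::tibble(
    sex = rep(rep(c("male", "female"), each = 6), 2),
    age_lo = rep(c(seq(40, 80, 10), 90), 4),
    age_hi = rep(c(seq(50, 90, 10), Inf), 4),
    site = rep(c("forearm", "humerus"), each = 12),
    events = c(
      38, 38, 20, 3, 2, 0,
      90, 172, 97, 53, 20, 3,
      13, 18, 15, 2, 0, 1,
      14, 35, 39, 21, 16, 0
    )
  )
  totals <- tibble::tibble(
    sex = c("male", "female", "male", "female"),
    site = c("forearm", "forearm", "humerus", "humerus"),
    events = c(101, 435, 49, 125),
    rate = c(197, 617, 95, 177),
    ci_low = c(160, 560, 71, 148),
    ci_high = c(239, 678, 126, 211)
  )
  pred_obs <- tibble::tibble(
    sex = rep(c("male", "female"), each = 8),
    age_lo = rep(rep(seq(50, 80, 10), 2), 2),
    age_hi = rep(rep(seq(60, 90, 10), 2), 2),
    site = rep(rep(c("forearm", "humerus"), each = 4), 2),
    predicted = c(
      298, 286, 85, 79, 113, 103, 128, 100,
      516, 497, 640, 507, 148, 188, 332, 338
    ),
    observed = c(
      229, 206, 78, 165, 109, 154, 52, 0,
      804, 673, 743, 748, 164, 271, 294, 599
    ),
    ci_low = c(
      162, 126, 16, 20, 64, 85, 6, 0,
      689, 546, 556, 457, 114, 192, 182, 342
    ),
    ci_high = c(
      315, 318, 226, 598, 172, 255, 187, 305,
      934, 821, 971, 1156, 228, 370, 450, 972
    ),
    flagged = c(
      rep(FALSE, 8),
      TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE
    )
  )
  constants <- list(
    fracture_total = 1058,
    hip_total = 348, forearm_total = 536, humerus_total = 174,
    hip_men = 134, hip_women = 214,
    hip_refused = 82, hip_admitted = 266, hip_surgical = 200,
    women_retro_annual = 65,
    women_prospective_annual = 84,
    women_additional = 19,
    men_uplift_pct = 8,
    women_adjusted_events = 252, men_adjusted_events = 141,
    women_person_years = 106880, men_person_years = 77949,
    women_adjusted_rate = 236, men_adjusted_rate = 181,
    women_adjusted_ci = c(207, 266), men_adjusted_ci = c(152, 213)
  )
  list(
    hip_incidence = hip,
    appendicular_counts = appendicular,
    appendicular_totals = totals,
    predicted_observed = pred_obs,
    constants = constants
  )
}
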