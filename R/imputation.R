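#' Impute a non-hip fracture rate from hip incidence via reference ratios
#'
#' Many fracture-risk models are built where only hip fracture incidence is
#' known locally. Assuming the local age- and sex-specific ratio of other
#' major osteoporotic fractures (OMF) to hip fracture (HF) equals that of a
#' well-characterised reference population (classically Malmo, Sweden), the
#' local OMF rate is
#'
#' \deqn{OMF_{local} = HF_{local} \times OMF_{ref} / HF_{ref}}
#'
#' @param hf_local Local hip fracture rate (>= 0).
#' @param hf_ref Reference hip fracture rate (> 0) for the same age/sex
#'   stratum.
#' @param omf_ref Reference rate of the target fracture site (>= 0).
#' @return Imputed local rate of the target site. Vectorised.
#' @examples
#' impute_omf_rate(200, 100, 350) # 700
#' @export
impute_omf_rate <- function(hf_local, hf_ref, omf_ref) {
  if (any(hf_ref <= 0)) abort_input("`hf_ref` must be > 0")
  if (any(hf_local < 0) || any(omf_ref < 0)) abort_input("rates must be >= 0")
  hf_local * omf_ref / hf_ref
}

#' Read a reference incidence table
#'
#' @param path CSV with columns `sex`, `age_lo`, `age_hi`, `site`, `rate`
#'   (per 100,000/year). An empty `age_hi` denotes the open terminal band.
#' @return Tibble with those columns.
#' @export
read_reference_table <- function(path) {
  ref <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      age_lo = readr::col_double(),
      age_hi = readr::col_double(),
      site = readr::col_character(),
      rate = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  ref$age_hi[is.na(ref$age_hi)] <- Inf
  ref
}

#' Predict non-hip incidence for every stratum of a reference table
#'
#' Applies [impute_omf_rate()] stratum by stratum: local hip rates are
#' matched to the reference hip rates on (sex, age band) and each non-hip
#' site of the reference table is scaled accordingly.
#'
#' @param local_hip Incidence table of local hip rates (columns `sex`,
#'   `age_lo`, `age_hi`, `rate`).
#' @param reference Reference table from [read_reference_table()], containing
#'   a `hip` site row for every stratum to be imputed.
#' @param sites Sites to impute (default: all non-hip sites present).
#' @return Tibble `sex`, `age_lo`, `age_hi`, `site`, `rate` of predicted
#'   local rates.
#' @export
impute_from_reference <- function(local_hip, reference, sites = NULL) {
  ref_hip <- reference[reference$site == "hip", c("sex", "age_lo", "age_hi", "rate")]
  if (nrow(ref_hip) == 0) abort_input("reference table has no 'hip' rows")
  if (is.null(sites)) sites <- setdiff(unique(reference$site), "hip")
  ref_omf <- reference[reference$site %in% sites, ]
  joined <- ref_omf |>
    dplyr::inner_join(
      dplyr::rename(ref_hip, hf_ref = "rate"),
      by = c("sex", "age_lo", "age_hi")
    ) |>
    dplyr::inner_join(
      dplyr::select(local_hip, "sex", "age_lo", "age_hi", hf_local = "rate"),
      by = c("sex", "age_lo", "age_hi")
    )
  dplyr::transmute(
    joined,
    sex = .data$sex, age_lo = .data$age_lo, age_hi = .data$age_hi,
    site = .data$site,
    rate = impute_omf_rate(.data$hf_local, .data$hf_ref, .data$rate)
  )
}

#' Compare predicted with observed incidence
#'
#' Joins predicted and observed rates on (sex, age band, site) and flags a
#' stratum as significantly different when the predicted rate falls outside
#' the exact 95% confidence interval of the observed rate — the
#' CI-exclusion rule used to mark discordant cells in published
#' predicted-vs-observed tables. Strata present on only one side are
#' returned with status `"missing"` rather than dropped.
#'
#' @param predicted Tibble `sex`, `age_lo`, `age_hi`, `site`, `rate`.
#' @param observed Incidence table with `rate`, `ci_low`, `ci_high`.
#' @return Tibble with one row per stratum: `predicted`, `observed`,
#'   `ci_low`, `ci_high`, `significant` (logical, `NA` when unmatched) and
#'   `status` (`"compared"` or `"missing"`).
#' @export
compare_predicted_observed <- function(predicted, observed) {
  pred <- dplyr::select(
    predicted, "sex", "age_lo", "age_hi", "site", predicted = "rate"
  )
  obs <- dplyr::select(
    observed, "sex", "age_lo", "age_hi", "site",
    observed = "rate", "ci_low", "ci_high"
  )
  out <- dplyr::full_join(
    pred, obs, by = c("sex", "age_lo", "age_hi", "site")
  )
  dplyr::mutate(
    out,
    significant = .data$predicted < .data$ci_low | .data$predicted > .data$ci_high,
    status = ifelse(is.na(.data$predicted) | is.na(.data$observed),
      "missing", "compared"
    )
  )
}
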