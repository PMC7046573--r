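#' Crude incidence rate
#'
#' @param events Number of events (may be fractional after capture
#'   adjustment).
#' @param person_years Person-years at risk (> 0).
#' @param per Population scale of the reported rate (default 100,000).
#' @return Rate per `per` person-years, unrounded. Vectorised.
#' @examples
#' crude_rate(252, 106880) # 235.78
#' @export
crude_rate <- function(events, person_years, per = 1e5) {
  if (any(person_years <= 0)) abort_input("`person_years` must be > 0")
  if (any(events < 0)) abort_input("`events` must be >= 0")
  events / person_years * per
}

#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' Exact two-sided confidence limits for a Poisson-distributed event count,
#' expressed per `per` person-years. The bounds are gamma quantiles on the
#' event scale — lower limit `qgamma(alpha/2, events)`, upper limit
#' `qgamma(1 - alpha/2, events + 1)` — divided by person-years. They invert
#' the Poisson tail probabilities, so coverage is guaranteed at or above the
#' nominal level. The lower bound is 0 when `events = 0`. Fractional event
#' counts (arising from capture adjustment) are supported through the
#' continuous gamma shapes.
#'
#' @inheritParams crude_rate
#' @param level Confidence level in (0, 1) (default 0.95).
#' @return Tibble with columns `ci_low`, `ci_high` on the rate scale.
#'   Vectorised over `events` / `person_years`.
#' @examples
#' exact_poisson_ci(141, 77949) # 152.3 - 213.3 per 100,000
#' exact_poisson_ci(5, 1, per = 1) # event-scale limits 1.62 - 11.67
#' @export
exact_poisson_ci <- function(events, person_years, level = 0.95, per = 1e5) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    abort_input("`level` must be a single number strictly between 0 and 1")
  }
  if (any(person_years <= 0)) abort_input("`person_years` must be > 0")
  if (any(events < 0)) abort_input("`events` must be >= 0")
  alpha <- 1 - level
  lo <- ifelse(events == 0, 0, stats::qgamma(alpha / 2, shape = events))
  hi <- stats::qgamma(1 - alpha / 2, shape = events + 1)
  tibble::tibble(
    ci_low = lo / person_years * per,
    ci_high = hi / person_years * per
  )
}

#' Capture (ascertainment) adjustment from a prospective phase
#'
#' Retrospective hospital-register surveillance misses cases that never reach
#' hospital sources. A prospective phase with additional primary-care
#' ascertainment measures the shortfall: if the registers yielded
#' `retro_annual_count` cases per year and the prospective phase found
#' `additional_prospective_count` more, retrospective years are uplifted by
#' the factor `(retro + additional) / retro`.
#'
#' @param retro_annual_count Annual case count from retrospective sources
#'   (> 0).
#' @param additional_prospective_count Additional cases found prospectively
#'   (>= 0).
#' @param years Calendar years the uplift applies to.
#' @param sex Optional label for the stratum the adjustment belongs to.
#' @return An object of class `"capture_adjustment"`: a list with `factor`,
#'   `uplift_pct` (rounded to integer), `years`, and the input counts.
#' @examples
#' capture_adjustment(65, 19, years = c(2015, 2016)) # factor 84/65, 29%
#' @export
capture_adjustment <- function(retro_annual_count, additional_prospective_count,
                               years = integer(), sex = NULL) {
  if (retro_annual_count <= 0) {
    abort_input("`retro_annual_count` must be > 0: the adjustment is undefined without retrospective cases")
  }
  if (additional_prospective_count < 0) {
    abort_input("`additional_prospective_count` must be >= 0")
  }
  factor <- (retro_annual_count + additional_prospective_count) / retro_annual_count
  structure(
    list(
      sex = sex,
      retro_annual_count = retro_annual_count,
      additional_prospective_count = additional_prospective_count,
      factor = factor,
      uplift_pct = round_half_away((factor - 1) * 100),
      years = as.integer(years)
    ),
    class = "capture_adjustment"
  )
}

#' @export
print.capture_adjustment <- function(x, ...) {
  cat(sprintf(
    "Capture adjustment%s: factor %.4f (+%d%%) for years %s\n",
    if (is.null(x$sex)) "" else paste0(" [", x$sex, "]"),
    x$factor, x$uplift_pct,
    if (length(x$years)) paste(x$years, collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' Apply a capture adjustment to annual event counts
#'
#' Multiplies the counts of the adjustment's years by its uplift factor;
#' other years are unchanged. Fractional results are carried unrounded so
#' that downstream rates and intervals use the adjusted counts exactly.
#'
#' @param counts_by_year Named numeric vector of event counts, names being
#'   calendar years.
#' @param adj A [capture_adjustment()] object.
#' @return Named numeric vector of adjusted counts.
#' @examples
#' apply_adjustment(
#'   c("2015" = 65, "2016" = 65, "2017" = 84),
#'   capture_adjustment(65, 19, years = c(2015, 2016))
#' )
#' @export
apply_adjustment <- function(counts_by_year, adj) {
  stopifnot(inherits(adj, "capture_adjustment"))
  if (is.null(names(counts_by_year))) {
    abort_input("`counts_by_year` must be named by calendar year")
  }
  yrs <- as.integer(names(counts_by_year))
  out <- counts_by_year
  out[yrs %in% adj$years] <- out[yrs %in% adj$years] * adj$factor
  out
}

#' Female/male event ratio
#'
#' @param female_events,male_events Event counts.
#' @return Ratio female/male rounded to 1 decimal, half away from zero;
#'   `NA` when `male_events` is 0 (ratio undefined).
#' @examples
#' female_male_ratio(214, 134) # 1.6
#' @export
female_male_ratio <- function(female_events, male_events) {
  ifelse(male_events == 0, NA_real_,
    round_half_away(female_events / male_events, 1)
  )
}

#' Build an incidence table from stratum counts
#'
#' @param counts Tibble with columns `sex`, `age_lo`, `age_hi`, `site`,
#'   `events`, `person_years`.
#' @param level Confidence level for the exact Poisson intervals.
#' @param adjusted Whether the event counts are capture-adjusted (recorded
#'   in the output).
#' @param per Rate scale (default per 100,000).
#' @return Tibble with the input columns plus `rate`, `ci_low`, `ci_high`
#'   and `adjusted`; carries the level and scale as attributes.
#' @export
incidence_table <- function(counts, level = 0.95, adjusted = FALSE, per = 1e5) {
  need <- c("sex", "age_lo", "age_hi", "site", "events", "person_years")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort_input("`counts` is missing column(s): ", paste(missing, collapse = ", "))
  }
  ci <- exact_poisson_ci(counts$events, counts$person_years, level, per)
  out <- dplyr::mutate(
    counts,
    rate = crude_rate(.data$events, .data$person_years, per),
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    adjusted = adjusted
  )
  attr(out, "level") <- level
  attr(out, "per") <- per
  out
}

#' Tabulate incidence from records and a population table
#'
#' Counts deduplicated eligible records per (sex, age band) stratum, obtains
#' the person-years denominator from the population table over the study
#' years, and returns the incidence table with exact intervals.
#'
#' @param records Filtered, deduplicated records.
#' @param pop Population tibble (see [read_population()]).
#' @param bands Age-band scheme from [age_bands()].
#' @param years Study years (person-years are summed over them).
#' @param site Site label for the output rows.
#' @inheritParams incidence_table
#' @return An incidence table (see [incidence_table()]).
#' @export
tabulate_incidence <- function(records, pop, bands, years, site = "hip",
                               level = 0.95, adjusted = FALSE, per = 1e5) {
  grid <- tidyr::expand_grid(sex = c("male", "female"), bands)
  grid$events <- mapply(
    function(s, lo, hi) {
      sum(records$sex == s & records$age >= lo & records$age < hi)
    },
    grid$sex, grid$age_lo, grid$age_hi
  )
  grid$person_years <- mapply(
    function(s, lo, hi) person_years(pop, s, lo, hi, years),
    grid$sex, grid$age_lo, grid$age_hi
  )
  grid$site <- site
  incidence_table(
    grid[, c("sex", "age_lo", "age_hi", "site", "events", "person_years")],
    level = level, adjusted = adjusted, per = per
  )
}

#' Aggregate an incidence table to a coarser age-band scheme
#'
#' Events and person-years are summed within each coarser band and the rate
#' and exact interval recomputed from the sums. Each coarser band must be an
#' exact union of consecutive finer bands.
#'
#' @param tab An incidence table.
#' @param scheme Coarser age-band scheme from [age_bands()].
#' @return Incidence table on the coarser scheme.
#' @export
aggregate_bands <- function(tab, scheme) {
  fine <- dplyr::distinct(tab[, c("age_lo", "age_hi")])
  if (!bands_nest_in(fine, scheme)) {
    abort_input("target scheme does not nest the table's age bands")
  }
  idx <- findInterval(tab$age_lo, scheme$age_lo)
  hi_ok <- tab$age_hi <= c(scheme$age_lo[-1], Inf)[idx]
  if (any(!hi_ok)) {
    abort_input("target scheme does not nest the table's age bands")
  }
  out <- tab |>
    dplyr::mutate(age_lo = scheme$age_lo[idx], age_hi = scheme$age_hi[idx]) |>
    dplyr::group_by(.data$sex, .data$site, .data$age_lo, .data$age_hi) |>
    dplyr::summarise(
      events = sum(.data$events),
      person_years = sum(.data$person_years),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sex, .data$site, .data$age_lo)
  incidence_table(
    out[, c("sex", "age_lo", "age_hi", "site", "events", "person_years")],
    level = attr(tab, "level") %||% 0.95,
    adjusted = isTRUE(tab$adjusted[1]),
    per = attr(tab, "per") %||% 1e5
  )
}

#' Care-pathway summary for hip fracture cases
#'
#' Summarises what happened to ascertained cases: the proportion who
#' formally refused hospital admission, the proportion of admitted patients
#' who underwent surgery, and the proportion of all cases left untreated or
#' managed conservatively (i.e. all cases minus the surgically treated).
#' Percentages are rounded half away from zero to integers, as reported.
#'
#' @param records Tibble of hip-fracture records with `admitted` and
#'   `surgical` columns.
#' @return List with counts (`n`, `refused`, `admitted`, `surgical`) and
#'   integer percentages (`pct_refused`, `pct_surgical_among_admitted`,
#'   `pct_untreated_or_conservative`). The surgical percentage is `NA` when
#'   no case was admitted.
#' @export
care_pathway_summary <- function(records) {
  n <- nrow(records)
  if (n == 0) abort_input("no records to summarise")
  refused <- sum(records$admitted == "refused")
  admitted <- sum(records$admitted == "admitted")
  surgical <- sum(records$admitted == "admitted" & records$surgical)
  list(
    n = n,
    refused = refused,
    admitted = admitted,
    surgical = surgical,
    pct_refused = round_half_away(100 * refused / n),
    pct_surgical_among_admitted =
      if (admitted == 0) NA_real_ else round_half_away(100 * surgical / admitted),
    pct_untreated_or_conservative = round_half_away(100 * (n - surgical) / n)
  )
}
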