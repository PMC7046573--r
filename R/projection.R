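#' Read a population projection table
#'
#' @param path CSV with columns `sex`, `age_lo`, `age_hi`, `year`,
#'   `population` (projected persons). An empty `age_hi` denotes the open
#'   terminal band.
#' @return Tibble with those columns.
#' @export
read_projection <- function(path) {
  pr <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      age_lo = readr::col_double(),
      age_hi = readr::col_double(),
      year = readr::col_integer(),
      population = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  pr$age_hi[is.na(pr$age_hi)] <- Inf
  if (any(pr$population < 0, na.rm = TRUE)) abort_input("projected populations must be >= 0")
  pr
}

#' Expected annual fracture count in a projected population
#'
#' Applies age- and sex-specific incidence to a projected population,
#' assuming the age- and sex-specific rates remain stable: the expected
#' count is the sum over age bands of `rate / per * population`. Every
#' populated band must have a matching rate.
#'
#' @param rates Incidence table (columns `sex`, `age_lo`, `age_hi`, `rate`).
#' @param pop Projection tibble (see [read_projection()]).
#' @param year Calendar year of the projection.
#' @param sex `"male"` or `"female"`.
#' @param min_age Lower age limit of the projection scope (default 50);
#'   younger strata are ignored.
#' @param per Scale of the table's rates (default per 100,000).
#' @return Expected fracture count (unrounded).
#' @export
expected_fractures <- function(rates, pop, year, sex, min_age = 50,
                               per = attr(rates, "per") %||% 1e5) {
  strata <- pop[pop$year == year & pop$sex == sex & pop$age_lo >= min_age, , drop = FALSE]
  if (nrow(strata) == 0) return(0)
  r <- rates[rates$sex == sex, c("age_lo", "age_hi", "rate")]
  joined <- dplyr::left_join(strata, r, by = c("age_lo", "age_hi"))
  if (anyNA(joined$rate)) {
    miss <- joined[is.na(joined$rate), ]
    abort_input(
      "no incidence rate for projected band(s): ",
      paste(sprintf("%s [%g, %g)", sex, miss$age_lo, miss$age_hi), collapse = ", ")
    )
  }
  sum(joined$rate / per * joined$population)
}

#' Project fracture counts over calendar years
#'
#' Expected fracture counts per calendar year and sex under stable age- and
#' sex-specific incidence, with percentage change relative to a base year.
#' Percent changes are computed from unrounded totals; counts are rounded
#' only in the returned report columns.
#'
#' @inheritParams expected_fractures
#' @param years Calendar years to project.
#' @param base_year Reference year for percent change (must be in `years`).
#' @return List of class `"projection_result"` with `by_sex` (tibble
#'   `year`, `sex`, `expected`, `pct_change`) and `total` (tibble `year`,
#'   `expected`, `pct_change`).
#' @export
project_series <- function(rates, pop, years, base_year, min_age = 50,
                           per = attr(rates, "per") %||% 1e5) {
  if (!base_year %in% years) abort_input("`base_year` must be one of `years`")
  grid <- tidyr::expand_grid(year = as.integer(years), sex = c("male", "female"))
  grid$expected <- mapply(
    function(y, s) expected_fractures(rates, pop, y, s, min_age = min_age, per = per),
    grid$year, grid$sex
  )
  base <- grid[grid$year == base_year, ]
  grid <- dplyr::mutate(
    grid,
    pct_change = (.data$expected /
      base$expected[match(.data$sex, base$sex)] - 1) * 100
  )
  total <- grid |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(expected = sum(.data$expected), .groups = "drop")
  total$pct_change <- (total$expected / total$expected[total$year == base_year] - 1) * 100
  structure(
    list(by_sex = grid, total = total, base_year = as.integer(base_year)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projected fracture counts (base year %d):\n", x$base_year))
  out <- dplyr::mutate(
    x$total,
    expected = round_half_away(.data$expected),
    pct_change = round_half_away(.data$pct_change)
  )
  print(as.data.frame(out), row.names = FALSE)
  invisible(x)
}
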