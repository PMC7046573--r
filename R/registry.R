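#' ICD-10 site code sets
#'
#' The fracture sites tracked by the pipeline and their ICD-10 codes:
#' hip (proximal femur) S72.0, S72.1, S72.2; distal forearm S52.5, S52.6;
#' proximal humerus S42.2.
#'
#' @return Named list of character vectors of ICD-10 codes.
#' @examples
#' site_codes()$hip
#' @export
site_codes <- function() {
  list(
    hip = c("S72.0", "S72.1", "S72.2"),
    forearm = c("S52.5", "S52.6"),
    humerus = c("S42.2")
  )
}

# map a normalised ICD-10 code to its site group label; codes outside the
# configured sets map to themselves so dedup never merges unknown sites
site_of <- function(icd10, sites = site_codes()) {
  lut <- stats::setNames(
    rep(names(sites), lengths(sites)),
    unlist(sites, use.names = FALSE)
  )
  out <- unname(lut[icd10])
  ifelse(is.na(out), icd10, out)
}

normalise_icd10 <- function(x) gsub("[[:space:]]", "", toupper(as.character(x)))

registry_columns <- c(
  "person_id", "sex", "age", "year", "icd10",
  "admitted", "surgical", "pathological", "resident", "radiograph"
)

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

parse_admitted <- function(x) {
  x <- gsub("[[:space:]-]", "_", tolower(trimws(as.character(x))))
  out <- rep(NA_character_, length(x))
  out[x == "admitted"] <- "admitted"
  out[x == "refused"] <- "refused"
  out[x == "not_presented"] <- "not_presented"
  out
}

#' Read a fracture registry file
#'
#' Reads a delimited text file of fracture case records (one row per
#' ascertained case) and validates every row. Rows that cannot be parsed are
#' never dropped silently: they are returned alongside the parsed records
#' with the reason for rejection, so that
#' `nrow(records) + nrow(rejections)` always equals the number of input rows.
#'
#' Required columns: `person_id`, `sex` (male/female), `age` (completed
#' years), `year` (calendar year of fracture), `icd10` (site code),
#' `admitted` (admitted / refused / not_presented), `surgical`,
#' `pathological`, `resident`, `radiograph` (logical flags).
#'
#' @param path Path to a delimited text file with a header.
#' @param delim Field delimiter (default comma).
#' @return A list with components `records` (tibble of parsed records, input
#'   order preserved) and `rejections` (tibble with `row` and `reason`).
#' @export
read_registry <- function(path, delim = ",") {
  if (!file.exists(path)) abort_input("registry file not found: ", path)
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(registry_columns, names(raw))
  if (length(missing) > 0) {
    abort_input(
      "registry file is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  parsed <- tibble::tibble(
    person_id = as.character(raw$person_id),
    sex = parse_sex(raw$sex),
    age = suppressWarnings(as.integer(raw$age)),
    year = suppressWarnings(as.integer(raw$year)),
    icd10 = normalise_icd10(raw$icd10),
    admitted = parse_admitted(raw$admitted),
    surgical = parse_flag(raw$surgical),
    pathological = parse_flag(raw$pathological),
    resident = parse_flag(raw$resident),
    radiograph = parse_flag(raw$radiograph)
  )
  reason <- dplyr::case_when(
    is.na(parsed$person_id) | parsed$person_id == "" ~ "missing person_id",
    is.na(parsed$sex) ~ "unparsable sex",
    is.na(parsed$age) | parsed$age < 0 ~ "unparsable age",
    is.na(parsed$year) ~ "unparsable year",
    parsed$icd10 == "" ~ "missing icd10",
    is.na(parsed$admitted) ~ "unparsable admission status",
    is.na(parsed$surgical) ~ "unparsable surgical flag",
    is.na(parsed$pathological) ~ "unparsable pathological flag",
    is.na(parsed$resident) ~ "unparsable resident flag",
    is.na(parsed$radiograph) ~ "unparsable radiograph flag",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  list(
    records = parsed[ok, , drop = FALSE],
    rejections = tibble::tibble(row = which(!ok), reason = reason[!ok])
  )
}

#' Filter records to the eligible case definition
#'
#' Applies the epidemiological case definition: fracture site within the
#' requested ICD-10 code set, age at fracture at or above `min_age`,
#' permanent resident of the catchment area, non-pathological fracture,
#' event year inside the study window, and radiographic confirmation.
#' All trauma levels are eligible (no high/low-energy distinction is made).
#'
#' In prospective surveillance mode some hip cases ascertained at home are
#' verified clinically only; set `accept_clinical = TRUE` to retain records
#' with `radiograph = FALSE`.
#'
#' The returned tibble carries an `"exclusions"` attribute tabulating how
#' many records each criterion removed (a record failing several criteria is
#' counted once, under the first in the order above), so that input rows are
#' fully accounted for.
#'
#' @param records Tibble of parsed records from [read_registry()].
#' @param sites Character vector of eligible ICD-10 codes.
#' @param min_age Minimum eligible age in completed years (default 40).
#' @param years Integer vector of eligible event years (default: all).
#' @param accept_clinical Retain clinically-verified cases without
#'   radiographs (default FALSE).
#' @return Filtered tibble of records, input order preserved, with an
#'   `"exclusions"` attribute (tibble of `reason`, `n`).
#' @export
filter_eligible <- function(records, sites, min_age = 40, years = NULL,
                            accept_clinical = FALSE) {
  if (length(sites) == 0) abort_input("`sites` must contain at least one ICD-10 code")
  sites <- normalise_icd10(sites)
  checks <- list(
    "site outside code set" = records$icd10 %in% sites,
    "below minimum age" = records$age >= min_age,
    "non-resident" = records$resident,
    "pathological fracture" = !records$pathological,
    "outside study window" = if (is.null(years)) rep(TRUE, nrow(records)) else records$year %in% years,
    "no radiographic confirmation" = records$radiograph | accept_clinical
  )
  fail_first <- rep(NA_character_, nrow(records))
  for (nm in names(checks)) {
    fail_first[is.na(fail_first) & !checks[[nm]]] <- nm
  }
  kept <- records[is.na(fail_first), , drop = FALSE]
  excl <- table(factor(fail_first, levels = names(checks)))
  attr(kept, "exclusions") <- tibble::tibble(
    reason = names(excl), n = as.integer(excl)
  )
  kept
}

#' Remove repeat admissions for the same fracture
#'
#' A person readmitted for the same fracture site within the observation
#' window must be counted once. Records are collapsed to one per
#' (person, site group); the earliest event year is kept, ties broken by
#' input order. Different sites (e.g. a hip and a forearm fracture in the
#' same person) are distinct events and both retained.
#'
#' @param records Tibble of filtered records.
#' @param sites Site code sets used to group ICD-10 codes (default
#'   [site_codes()]); codes outside the sets group by their own code.
#' @return Deduplicated tibble, ordered as the retained input rows.
#' @export
deduplicate <- function(records, sites = site_codes()) {
  if (nrow(records) == 0) return(records)
  grp <- site_of(records$icd10, sites)
  key <- paste(records$person_id, grp, sep = "\r")
  ord <- order(key, records$year, seq_len(nrow(records)))
  first <- !duplicated(key[ord])
  keep <- sort(seq_len(nrow(records))[ord][first])
  records[keep, , drop = FALSE]
}

#' Read a population denominator table
#'
#' @param path CSV with columns `sex`, `age_lo`, `age_hi`, `year`, `count`
#'   (annual population of the stratum). An empty `age_hi` denotes the open
#'   terminal band.
#' @return Tibble with those columns (`age_hi` numeric, `Inf` when open).
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      age_lo = readr::col_double(),
      age_hi = readr::col_double(),
      year = readr::col_integer(),
      count = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  pop$age_hi[is.na(pop$age_hi)] <- Inf
  if (any(pop$count < 0, na.rm = TRUE)) abort_input("population counts must be >= 0")
  pop
}

#' Person-years at risk for one stratum
#'
#' Sums annual stratum populations over a range of calendar years; with
#' annual census counts this is the standard person-years denominator
#' (each resident contributes one person-year per year). The requested age
#' range may span several population bands provided they tile it exactly.
#'
#' @param pop Population tibble (`sex`, `age_lo`, `age_hi`, `year`, `count`).
#' @param sex `"male"` or `"female"`.
#' @param age_lo,age_hi Age range `[age_lo, age_hi)`; `age_hi = Inf` for an
#'   open band.
#' @param years Calendar years to sum over.
#' @param fallback Either `"none"` (a missing cell is an error) or
#'   `"nearest"` (replicate the band's count from the nearest available
#'   year).
#' @return Person-years (scalar).
#' @export
person_years <- function(pop, sex, age_lo, age_hi = Inf, years,
                         fallback = c("none", "nearest")) {
  fallback <- match.arg(fallback)
  sub <- pop[pop$sex == sex & pop$age_lo >= age_lo & pop$age_hi <= age_hi, , drop = FALSE]
  bands <- dplyr::distinct(sub[, c("age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), , drop = FALSE]
  covers <- nrow(bands) > 0 &&
    bands$age_lo[1] == age_lo &&
    bands$age_hi[nrow(bands)] == age_hi &&
    (nrow(bands) == 1 || all(bands$age_hi[-nrow(bands)] == bands$age_lo[-1]))
  if (!covers) {
    abort_input(sprintf(
      "population table does not tile ages [%s, %s) for sex '%s'",
      age_lo, age_hi, sex
    ))
  }
  total <- 0
  for (b in seq_len(nrow(bands))) {
    cell <- sub[sub$age_lo == bands$age_lo[b], , drop = FALSE]
    for (y in years) {
      hit <- cell$count[cell$year == y]
      if (length(hit) == 0) {
        if (fallback == "none") {
          abort_input(sprintf(
            "missing population cell: sex '%s', ages [%s, %s), year %d",
            sex, bands$age_lo[b], bands$age_hi[b], y
          ))
        }
        hit <- cell$count[which.min(abs(cell$year - y))]
        if (length(hit) == 0) {
          abort_input(sprintf(
            "no population data at all for sex '%s', ages [%s, %s)",
            sex, bands$age_lo[b], bands$age_hi[b]
          ))
        }
      }
      total <- total + hit[1]
    }
  }
  total
}
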