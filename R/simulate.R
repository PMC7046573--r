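#' Configuration for the synthetic registry generator
#'
#' Defines the ground truth of a simulated catchment-area fracture registry:
#' the population structure, parametric true incidence curves per site and
#' sex, hospital-capture probabilities below 1 (so that retrospective
#' register counts under-ascertain), care-pathway probabilities, duplicate
#' re-admissions, pathological-fracture contaminants and a Gompertz
#' mortality schedule. Defaults emulate a regional catchment of roughly
#' 165,000 people observed for three years, yielding about 350 hip
#' fractures, with hip capture fractions of 65/84 (women) and 1/1.08 (men)
#' so that the standard prospective-phase uplifts of 29% and 8% recover the
#' true rates.
#'
#' True incidence follows `rate(age) = rate50 * 2^((age - 50) / doubling)`
#' per 100,000/year (a constant rate when `doubling = Inf`). Mortality is
#' Gompertz, `h(a) = alpha * exp(beta * a)`, with defaults giving a life
#' expectancy at 50 of about 25 years (women) and 20 years (men).
#'
#' @param seed Integer seed; a fixed seed makes the generator output
#'   byte-identical.
#' @param years Calendar years of hip surveillance.
#' @param appendicular_years Calendar years of forearm/humerus surveillance.
#' @param prospective Named list: for each site, the years in which missed
#'   cases are additionally found through primary-care sources (written to
#'   the registry as `not_presented`).
#' @param sites Sites to simulate.
#' @param population Annual population tibble (`sex`, `age_lo`, `age_hi`,
#'   `year`, `count`); default: the packaged catchment structure replicated
#'   over `years`.
#' @param incidence Tibble `site`, `sex`, `rate50`, `doubling` of true
#'   incidence parameters.
#' @param capture Tibble `site`, `sex`, `p` of hospital-capture
#'   probabilities.
#' @param refusal_prob Probability a captured case formally refuses
#'   admission.
#' @param surgical_prob Probability an admitted case is treated surgically.
#' @param duplicate_prob Probability a written case generates a duplicate
#'   re-admission row for the same fracture.
#' @param pathological_rate Annual rate (per 100,000) of pathological
#'   fracture contaminants, which carry `pathological = TRUE`.
#' @param clinical_only_prob Probability a primary-care-ascertained case is
#'   verified clinically only (`radiograph = FALSE`).
#' @param gompertz Tibble `sex`, `alpha`, `beta` of mortality parameters.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              years = 2015:2017,
                              appendicular_years = 2015:2016,
                              prospective = list(hip = 2017L),
                              sites = c("hip", "forearm", "humerus"),
                              population = NULL,
                              incidence = NULL,
                              capture = NULL,
                              refusal_prob = 82 / 348,
                              surgical_prob = 200 / 266,
                              duplicate_prob = 0.05,
                              pathological_rate = 2,
                              clinical_only_prob = 0.5,
                              gompertz = NULL) {
  probs <- c(refusal_prob, surgical_prob, duplicate_prob, clinical_only_prob)
  if (any(probs < 0 | probs > 1)) abort_input("probabilities must lie in [0, 1]")
  if (pathological_rate < 0) abort_input("`pathological_rate` must be >= 0")
  if (is.null(population)) {
    hip_py <- fixture_tables()$hip_incidence
    population <- tidyr::expand_grid(
      hip_py[, c("sex", "age_lo", "age_hi")],
      year = as.integer(years)
    )
    population$count <- round(
      hip_py$person_years[match(
        paste(population$sex, population$age_lo),
        paste(hip_py$sex, hip_py$age_lo)
      )] / length(years)
    )
  }
  if (is.null(incidence)) {
    incidence <- tibble::tribble(
      ~site, ~sex, ~rate50, ~doubling,
      "hip", "female", 53.405, 7,
      "hip", "male", 97.188, 11,
      "forearm", "female", 610.498, Inf,
      "forearm", "male", 194.358, Inf,
      "humerus", "female", 175.430, Inf,
      "humerus", "male", 94.292, Inf
    )
  }
  if (is.null(capture)) {
    capture <- tibble::tribble(
      ~site, ~sex, ~p,
      "hip", "female", 65 / 84,
      "hip", "male", 1 / 1.08,
      "forearm", "female", 1, "forearm", "male", 1,
      "humerus", "female", 1, "humerus", "male", 1
    )
  }
  if (any(capture$p < 0 | capture$p > 1)) abort_input("capture probabilities must lie in [0, 1]")
  if (is.null(gompertz)) {
    # alpha solved so that e50 = 25 y (women) / 20 y (men) at beta = 0.10
    gompertz <- tibble::tibble(
      sex = c("female", "male"),
      alpha = c(3.757356e-05, 6.862815e-05),
      beta = c(0.10, 0.10)
    )
  }
  structure(
    list(
      seed = as.integer(seed), years = as.integer(years),
      appendicular_years = as.integer(appendicular_years),
      prospective = prospective, sites = sites,
      population = population, incidence = incidence, capture = capture,
      refusal_prob = refusal_prob, surgical_prob = surgical_prob,
      duplicate_prob = duplicate_prob, pathological_rate = pathological_rate,
      clinical_only_prob = clinical_only_prob, gompertz = gompertz
    ),
    class = "simulation_config"
  )
}

true_rate <- function(incidence, site, sex, age) {
  row <- incidence[incidence$site == site & incidence$sex == sex, ]
  if (nrow(row) == 0) abort_input("no incidence parameters for ", site, "/", sex)
  row$rate50[1] * 2^((age - 50) / row$doubling[1])
}

site_years_of <- function(config, site) {
  if (site == "hip") config$years else config$appendicular_years
}

#' Simulate a catchment fracture registry with known ground truth
#'
#' Per (site, year, sex, age band) stratum the number of true incident
#' fractures is drawn as Poisson(rate x population); each case is captured
#' by hospital sources with the stratum's capture probability. Captured
#' cases receive admission, refusal and surgical flags; in prospective
#' years the missed cases are also written (as ascertained via primary
#' care, `admitted = "not_presented"`, sometimes verified clinically only).
#' Duplicate re-admission rows and pathological contaminants are injected
#' so that the cleaning pipeline has real work to do. The same seed
#' reproduces the output exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `registry` (case tibble in registry-file column
#'   layout), `population` (annual denominators), `life_table` (tibble
#'   `sex`, `age`, `death_hazard` from the Gompertz parameters, ages
#'   40-109) and `ground_truth` (list: per-stratum `true_rates` with
#'   expected event counts, the `capture` table and the seed).
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  codes <- site_codes()
  bands <- dplyr::distinct(config$population[, c("age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), ]
  rows <- list()
  truth <- list()
  next_id <- 1L
  for (site in config$sites) {
    yrs <- site_years_of(config, site)
    pro_yrs <- config$prospective[[site]] %||% integer()
    for (sex in c("male", "female")) {
      p_cap <- config$capture$p[config$capture$site == site & config$capture$sex == sex]
      if (length(p_cap) == 0) p_cap <- 1
      for (b in seq_len(nrow(bands))) {
        lo <- bands$age_lo[b]
        hi <- min(bands$age_hi[b], lo + 5)
        mid <- (lo + hi) / 2
        rate <- true_rate(config$incidence, site, sex, mid)
        exp_events <- 0
        for (y in yrs) {
          popn <- config$population$count[
            config$population$sex == sex &
              config$population$age_lo == lo &
              config$population$year == y
          ]
          if (length(popn) == 0) next
          lambda <- rate / 1e5 * popn[1]
          exp_events <- exp_events + lambda
          n_true <- stats::rpois(1, lambda)
          if (n_true == 0) next
          captured <- stats::rbinom(1, n_true, p_cap)
          missed_found <- if (y %in% pro_yrs) n_true - captured else 0L
          n_row <- captured + missed_found
          if (n_row == 0) next
          ids <- sprintf("P%06d", next_id:(next_id + n_row - 1L))
          next_id <- next_id + n_row
          age <- floor(stats::runif(n_row, lo, hi))
          refused <- c(
            stats::runif(captured) < config$refusal_prob,
            rep(FALSE, missed_found)
          )
          admitted <- rep("not_presented", n_row)
          admitted[seq_len(captured)] <- ifelse(refused[seq_len(captured)], "refused", "admitted")
          surgical <- admitted == "admitted" &
            stats::runif(n_row) < config$surgical_prob
          radiograph <- rep(TRUE, n_row)
          if (missed_found > 0) {
            radiograph[captured + seq_len(missed_found)] <-
              stats::runif(missed_found) >= config$clinical_only_prob
          }
          stratum <- tibble::tibble(
            person_id = ids, sex = sex, age = as.integer(age),
            year = as.integer(y),
            icd10 = sample(codes[[site]], n_row, replace = TRUE),
            admitted = admitted, surgical = surgical,
            pathological = FALSE, resident = TRUE, radiograph = radiograph
          )
          dup <- which(stats::runif(n_row) < config$duplicate_prob)
          if (length(dup) > 0) {
            extra <- stratum[dup, ]
            extra$admitted <- "admitted"
            extra$surgical <- FALSE
            stratum <- dplyr::bind_rows(stratum, extra)
          }
          rows[[length(rows) + 1L]] <- stratum
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          site = site, sex = sex,
          age_lo = bands$age_lo[b], age_hi = bands$age_hi[b],
          rate = rate, expected_events = exp_events
        )
      }
    }
  }
  # pathological contaminants: hip-coded, excluded downstream via the flag
  for (sex in c("male", "female")) {
    for (y in config$years) {
      popn <- sum(config$population$count[
        config$population$sex == sex & config$population$year == y
      ])
      n_path <- stats::rpois(1, config$pathological_rate / 1e5 * popn)
      if (n_path == 0) next
      ids <- sprintf("P%06d", next_id:(next_id + n_path - 1L))
      next_id <- next_id + n_path
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = ids, sex = sex,
        age = as.integer(floor(stats::runif(n_path, 40, 95))),
        year = as.integer(y),
        icd10 = sample(codes$hip, n_path, replace = TRUE),
        admitted = "admitted", surgical = FALSE,
        pathological = TRUE, resident = TRUE, radiograph = TRUE
      )
    }
  }
  lt <- tidyr::expand_grid(sex = c("female", "male"), age = 40:109)
  g <- config$gompertz
  lt$death_hazard <- g$alpha[match(lt$sex, g$sex)] *
    exp(g$beta[match(lt$sex, g$sex)] * lt$age)
  list(
    registry = dplyr::bind_rows(rows),
    population = config$population,
    life_table = lt,
    ground_truth = list(
      true_rates = dplyr::bind_rows(truth),
      capture = config$capture,
      seed = config$seed
    )
  )
}

#' Write a simulated data set to disk
#'
#' @param sim Result of [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of `registry.csv`, `population.csv`,
#'   `life_table.csv` and `ground_truth.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    registry = file.path(dir, "registry.csv"),
    population = file.path(dir, "population.csv"),
    life_table = file.path(dir, "life_table.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(sim$registry, paths["registry"])
  readr::write_csv(sim$population, paths["population"])
  readr::write_csv(sim$life_table, paths["life_table"])
  jsonlite::write_json(
    sim$ground_truth, paths["ground_truth"],
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
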