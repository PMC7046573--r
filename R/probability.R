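#' Piecewise-constant hazard curve
#'
#' A hazard curve holds an annual hazard (events per person-year) that is
#' constant on each interval `[knots[i], knots[i+1])`; the last value is
#' held constant beyond the final knot up to `terminal_age`. Ages below the
#' first knot are outside the curve's support.
#'
#' @param knots Ages (years), strictly increasing.
#' @param hazard Annual hazard at each knot (>= 0), same length as `knots`.
#' @param sex Optional label.
#' @param terminal_age Age at which the curve (and any integration over it)
#'   ends (default 110).
#' @return An object of class `"hazard_curve"`.
#' @examples
#' hazard_curve(c(50, 60, 70), c(0.001, 0.003, 0.01))
#' @export
hazard_curve <- function(knots, hazard, sex = NULL, terminal_age = 110) {
  if (length(knots) != length(hazard) || length(knots) == 0) {
    abort_input("`knots` and `hazard` must be non-empty and of equal length")
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    abort_input("`knots` must be strictly increasing")
  }
  if (any(hazard < 0)) abort_input("hazards must be >= 0")
  if (terminal_age <= max(knots)) {
    abort_input("`terminal_age` must exceed the last knot")
  }
  structure(
    list(
      knots = as.numeric(knots), hazard = as.numeric(hazard),
      sex = sex, terminal_age = terminal_age
    ),
    class = "hazard_curve"
  )
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf(
    "Piecewise-constant hazard curve%s: %d knots on [%g, %g), terminal age %g\n",
    if (is.null(x$sex)) "" else paste0(" [", x$sex, "]"),
    length(x$knots), min(x$knots), max(x$knots), x$terminal_age
  ))
  invisible(x)
}

#' Evaluate a hazard curve
#'
#' @param curve A [hazard_curve()].
#' @param age Ages (years) at which to evaluate; must lie in
#'   `[first knot, terminal_age)`.
#' @return Annual hazard at each age.
#' @export
hazard_at <- function(curve, age) {
  if (any(age < curve$knots[1]) || any(age >= curve$terminal_age)) {
    abort_input(sprintf(
      "hazard curve does not cover the requested ages (support [%g, %g))",
      curve$knots[1], curve$terminal_age
    ))
  }
  curve$hazard[findInterval(age, curve$knots)]
}

#' Hazard curve from an incidence table
#'
#' Converts tabulated band rates (per `per` person-years) for one sex into
#' an annual first-fracture hazard, piecewise constant on the age bands,
#' with the terminal band's rate held to `terminal_age`.
#'
#' @param tab Incidence table (columns `sex`, `age_lo`, `rate`).
#' @param sex Which sex's rows to use.
#' @param per Scale of the table's rates (default per 100,000).
#' @param terminal_age See [hazard_curve()].
#' @return A [hazard_curve()].
#' @export
hazard_from_incidence <- function(tab, sex, per = attr(tab, "per") %||% 1e5,
                                  terminal_age = 110) {
  rows <- tab[tab$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0) abort_input("no rows for sex '", sex, "' in the incidence table")
  rows <- rows[order(rows$age_lo), , drop = FALSE]
  hazard_curve(rows$age_lo, rows$rate / per, sex = sex, terminal_age = terminal_age)
}

#' Read a life table
#'
#' @param path CSV with columns `sex`, `age` and either `death_hazard`
#'   (annual mortality hazard) or `death_probability` (annual probability of
#'   death, converted to a hazard via `-log(1 - q)`).
#' @return Tibble `sex`, `age`, `death_hazard`.
#' @export
read_life_table <- function(path) {
  lt <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_double(), sex = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!"death_hazard" %in% names(lt)) {
    if (!"death_probability" %in% names(lt)) {
      abort_input("life table needs a `death_hazard` or `death_probability` column")
    }
    if (any(lt$death_probability < 0 | lt$death_probability >= 1)) {
      abort_input("`death_probability` must lie in [0, 1)")
    }
    lt$death_hazard <- -log(1 - lt$death_probability)
  }
  lt[, c("sex", "age", "death_hazard")]
}

#' Death-hazard curve from a life table
#'
#' @param life_table Tibble from [read_life_table()] (or with the same
#'   columns).
#' @param sex Which sex's schedule to use.
#' @param terminal_age See [hazard_curve()].
#' @return A [hazard_curve()] of annual death hazards.
#' @export
life_table_hazard <- function(life_table, sex, terminal_age = 110) {
  rows <- life_table[life_table$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0) abort_input("no life-table rows for sex '", sex, "'")
  rows <- rows[order(rows$age), , drop = FALSE]
  rows <- rows[rows$age < terminal_age, , drop = FALSE]
  hazard_curve(rows$age, rows$death_hazard, sex = sex, terminal_age = terminal_age)
}

#' Cumulative incidence of first fracture under competing mortality
#'
#' Probability of sustaining a first fracture before death and before the
#' horizon, for a person fracture-free at `start_age`:
#' \deqn{P = \int_0^T r\,h_f(t)\, e^{-\int_0^t (r\,h_f(u) + h_d(u))\,du}\,dt}
#' where \eqn{h_f} is the annual first-fracture hazard, \eqn{h_d} the annual
#' death hazard and \eqn{r} a proportional hazard-ratio multiplier (e.g. a
#' prior-fracture risk profile). Both hazards are piecewise constant, so the
#' integral is evaluated in closed form on each constant-hazard segment
#' (segments split at every knot of either curve and at the horizon) and
#' summed — no numerical quadrature is involved.
#'
#' @param fracture_hazard,death_hazard [hazard_curve()] objects covering
#'   `[start_age, start_age + horizon)` (integration is truncated at the
#'   curves' terminal age).
#' @param start_age Age at assessment (years).
#' @param horizon Horizon in years (> 0).
#' @param rr Hazard-ratio multiplier applied to the fracture hazard
#'   (default 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' f <- hazard_curve(40, 0.01)
#' d <- hazard_curve(40, 0.02)
#' cumulative_incidence(f, d, start_age = 50, horizon = 10) # 0.0864
#' @export
cumulative_incidence <- function(fracture_hazard, death_hazard,
                                 start_age, horizon, rr = 1) {
  if (horizon <= 0) abort_input("`horizon` must be > 0")
  if (rr < 0) abort_input("`rr` must be >= 0")
  end_age <- min(
    start_age + horizon,
    fracture_hazard$terminal_age, death_hazard$terminal_age
  )
  if (end_age <= start_age) return(0)
  if (start_age < fracture_hazard$knots[1] || start_age < death_hazard$knots[1]) {
    abort_input("hazard curves do not cover the assessment age")
  }
  cuts <- sort(unique(c(
    start_age, end_age,
    fracture_hazard$knots[fracture_hazard$knots > start_age &
      fracture_hazard$knots < end_age],
    death_hazard$knots[death_hazard$knots > start_age &
      death_hazard$knots < end_age]
  )))
  surv <- 1
  prob <- 0
  for (i in seq_len(length(cuts) - 1)) {
    dt <- cuts[i + 1] - cuts[i]
    f <- rr * hazard_at(fracture_hazard, cuts[i])
    d <- hazard_at(death_hazard, cuts[i])
    lam <- f + d
    if (lam > 0) {
      decay <- exp(-lam * dt)
      prob <- prob + surv * (f / lam) * (1 - decay)
      surv <- surv * decay
    }
  }
  prob
}

probability_result <- function(age, sex, horizon, rr, probability) {
  tibble::tibble(
    age = age, sex = sex %||% NA_character_, horizon = horizon,
    rr = rr, probability = probability
  )
}

#' 10-year fracture probability
#'
#' Builds the first-fracture hazard from an incidence table and the death
#' hazard from a life table, then computes the probability of fracture
#' before death within 10 years via [cumulative_incidence()].
#'
#' @param incidence Incidence table (per 100,000 band rates) for the index
#'   fracture site.
#' @param life_table Life table tibble (see [read_life_table()]).
#' @param age Age at assessment (>= first tabulated age).
#' @param sex `"male"` or `"female"`.
#' @param rr Hazard-ratio multiplier for the risk profile (default 1).
#' @param horizon Horizon in years (default 10).
#' @param terminal_age Upper age limit of the model (default 110).
#' @return One-row tibble: `age`, `sex`, `horizon`, `rr`, `probability`.
#' @export
ten_year_probability <- function(incidence, life_table, age, sex, rr = 1,
                                 horizon = 10, terminal_age = 110) {
  hf <- hazard_from_incidence(incidence, sex, terminal_age = terminal_age)
  hd <- life_table_hazard(life_table, sex, terminal_age = terminal_age)
  p <- cumulative_incidence(hf, hd, start_age = age, horizon = horizon, rr = rr)
  probability_result(age, sex, as.character(horizon), rr, p)
}

#' Remaining lifetime fracture probability
#'
#' Probability of sustaining the index fracture at any age after
#' `from_age`, accounting for competing mortality: the cumulative incidence
#' is integrated from `from_age` to the model's terminal age, by which
#' point the death hazard has driven the event-free survival — and hence
#' the integrand — to practical zero.
#'
#' @inheritParams ten_year_probability
#' @param from_age Age at assessment (default 50).
#' @return One-row tibble with `horizon = "lifetime"`.
#' @export
lifetime_risk <- function(incidence, life_table, from_age = 50, sex,
                          rr = 1, terminal_age = 110) {
  hf <- hazard_from_incidence(incidence, sex, terminal_age = terminal_age)
  hd <- life_table_hazard(life_table, sex, terminal_age = terminal_age)
  p <- cumulative_incidence(
    hf, hd,
    start_age = from_age, horizon = terminal_age - from_age, rr = rr
  )
  probability_result(from_age, sex, "lifetime", rr, p)
}
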