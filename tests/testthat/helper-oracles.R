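# Shared helpers: record builders and independent numerical oracles.

make_records <- function(n = 1, person_id = sprintf("P%03d", seq_len(n)),
                         sex = "female", age = 75L, year = 2015L,
                         icd10 = "S72.0", admitted = "admitted",
                         surgical = TRUE, pathological = FALSE,
                         resident = TRUE, radiograph = TRUE) {
  tibble::tibble(
    person_id = person_id, sex = sex, age = as.integer(age),
    year = as.integer(year), icd10 = icd10, admitted = admitted,
    surgical = surgical, pathological = pathological,
    resident = resident, radiograph = radiograph
  )
}

write_registry_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path)
  path
}

# Independent exact-interval oracle: invert the Poisson tail probabilities
# numerically (no gamma quantiles). Event-scale limits.
oracle_poisson_limits <- function(k, level = 0.95) {
  alpha <- 1 - level
  lo <- if (k == 0) 0 else {
    stats::uniroot(
      function(l) 1 - stats::ppois(k - 1, l) - alpha / 2,
      c(1e-12, 10 * k + 50), tol = 1e-12
    )$root
  }
  hi <- stats::uniroot(
    function(l) stats::ppois(k, l) - alpha / 2,
    c(1e-12, 10 * k + 100), tol = 1e-12
  )$root
  c(lo, hi)
}

# Independent cumulative-incidence oracle: fine-grid trapezoid integration
# of the integrand rr*h_f(t) * exp(-Lambda(t)), with the cumulative
# combined hazard Lambda accumulated segment by segment so that grid points
# align with every hazard knot.
oracle_cuminc <- function(fc, dc, start_age, horizon, rr = 1, step = 1e-4) {
  end_age <- min(start_age + horizon, fc$terminal_age, dc$terminal_age)
  cuts <- sort(unique(c(
    start_age, end_age,
    fc$knots[fc$knots > start_age & fc$knots < end_age],
    dc$knots[dc$knots > start_age & dc$knots < end_age]
  )))
  total <- 0
  big_lambda <- 0
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]
    b <- cuts[i + 1]
    m <- max(2L, ceiling((b - a) / step) + 1L)
    t <- seq(a, b, length.out = m)
    f <- rr * osteoepi::hazard_at(fc, a)
    d <- osteoepi::hazard_at(dc, a)
    lam <- f + d
    integrand <- f * exp(-(big_lambda + lam * (t - a)))
    h <- (b - a) / (m - 1)
    total <- total + h * (sum(integrand) - (integrand[1] + integrand[m]) / 2)
    big_lambda <- big_lambda + lam * (b - a)
  }
  total
}

# random piecewise-constant hazard pair on knots every 5 years from 50
random_hazard_pair <- function(terminal_age = 110) {
  knots <- seq(50, 100, by = 5)
  list(
    f = osteoepi::hazard_curve(
      knots, stats::runif(length(knots), 0, 0.05),
      terminal_age = terminal_age
    ),
    d = osteoepi::hazard_curve(
      knots, stats::runif(length(knots), 0, 0.2),
      terminal_age = terminal_age
    )
  )
}
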