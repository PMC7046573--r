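test_that("constant-hazard probabilities match the closed form exactly", {
  f <- hazard_curve(40, 0.01)
  d <- hazard_curve(40, 0.02)
  zero <- hazard_curve(40, 0)
  expect_equal(
    cumulative_incidence(f, d, 50, 10),
    (0.01 / 0.03) * (1 - exp(-0.3)),
    tolerance = 1e-12
  )
  expect_equal(
    cumulative_incidence(f, zero, 50, 10),
    1 - exp(-0.1),
    tolerance = 1e-12
  )
  expect_equal(cumulative_incidence(zero, d, 50, 10), 0)
})

test_that("piecewise curves agree with a fine-grid numerical oracle", {
  set.seed(77)
  for (i in 1:8) {
    hz <- random_hazard_pair()
    rr <- sample(c(1, 1.8, 2.6), 1)
    start <- sample(c(50, 57.5, 70), 1)
    horizon <- sample(c(10, 25.3, 60), 1)
    got <- cumulative_incidence(hz$f, hz$d, start, horizon, rr = rr)
    want <- oracle_cuminc(hz$f, hz$d, start, horizon, rr = rr)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("probabilities stay in [0,1] and respond monotonically", {
  set.seed(5)
  for (i in 1:10) {
    hz <- random_hazard_pair()
    p10 <- cumulative_incidence(hz$f, hz$d, 55, 10)
    p20 <- cumulative_incidence(hz$f, hz$d, 55, 20)
    expect_gte(p10, 0)
    expect_lte(p20, 1)
    expect_lte(p10, p20) # non-decreasing in horizon
    # doubling the hazard ratio increases the probability but less than 2x
    p_rr <- cumulative_incidence(hz$f, hz$d, 55, 10, rr = 2)
    if (p10 > 0) {
      expect_gt(p_rr, p10)
      expect_lt(p_rr, 2 * p10)
    }
    # a pointwise-larger fracture hazard cannot lower the probability
    f_up <- hazard_curve(hz$f$knots, hz$f$hazard * 1.3)
    expect_gte(cumulative_incidence(f_up, hz$d, 55, 10), p10)
    # a pointwise-larger death hazard cannot raise it
    d_up <- hazard_curve(hz$d$knots, hz$d$hazard + 0.05)
    expect_lte(cumulative_incidence(hz$f, d_up, 55, 10), p10)
  }
})

test_that("probability decomposes across a split of the horizon", {
  set.seed(13)
  for (i in 1:6) {
    hz <- random_hazard_pair()
    s <- 7.3
    T <- 22
    whole <- cumulative_incidence(hz$f, hz$d, 50, T)
    first <- cumulative_incidence(hz$f, hz$d, 50, s)
    rest <- cumulative_incidence(hz$f, hz$d, 50 + s, T - s)
    # event-free survival to 50 + s, from the curves directly
    cuts <- sort(unique(c(
      50, 50 + s,
      hz$f$knots[hz$f$knots > 50 & hz$f$knots < 50 + s],
      hz$d$knots[hz$d$knots > 50 & hz$d$knots < 50 + s]
    )))
    lam <- hazard_at(hz$f, cuts[-length(cuts)]) + hazard_at(hz$d, cuts[-length(cuts)])
    surv <- exp(-sum(lam * diff(cuts)))
    expect_equal(whole, first + surv * rest, tolerance = 1e-12)
  }
})

test_that("the 10-year probability wires incidence and life tables together", {
  tab <- incidence_table(tibble::tibble(
    sex = "female", age_lo = c(50, 60, 70), age_hi = c(60, 70, Inf),
    site = "hip", events = c(10, 40, 200), person_years = rep(1e5, 3)
  ))
  lt <- tibble::tibble(sex = "female", age = 50:109, death_hazard = 0.02)
  res <- ten_year_probability(tab, lt, age = 65, sex = "female")
  # hand-built equivalent: 5 years at 4e-4, 5 years at 2e-3, death 0.02
  f <- hazard_curve(c(50, 60, 70), c(1e-4, 4e-4, 2e-3))
  d <- hazard_curve(50, 0.02)
  expect_equal(res$probability, cumulative_incidence(f, d, 65, 10), tolerance = 1e-12)
  expect_equal(res$horizon, "10")
  # zero incidence gives zero probability
  zero_tab <- dplyr::mutate(tab, events = 0, rate = 0, ci_low = 0, ci_high = 0)
  expect_equal(
    ten_year_probability(zero_tab, lt, 65, "female")$probability, 0
  )
})

test_that("lifetime risk reduces to 1 - exp(-H) without mortality", {
  tab <- incidence_table(tibble::tibble(
    sex = "male", age_lo = 50, age_hi = Inf, site = "hip",
    events = 1000, person_years = 1e5
  ))
  lt <- tibble::tibble(sex = "male", age = 50:109, death_hazard = 0)
  res <- lifetime_risk(tab, lt, from_age = 50, sex = "male", terminal_age = 110)
  expect_equal(res$probability, 1 - exp(-0.01 * 60), tolerance = 1e-12)
  expect_equal(res$horizon, "lifetime")
})

test_that("the terminal-age truncation is numerically irrelevant under real mortality", {
  tab <- incidence_table(tibble::tibble(
    sex = "female", age_lo = 50, age_hi = Inf, site = "hip",
    events = 2000, person_years = 1e5
  ))
  lt <- tibble::tibble(
    sex = "female", age = 50:109,
    death_hazard = pmax(0.3, 0.01 * exp(0.08 * (50:109 - 50)))
  )
  p100 <- lifetime_risk(tab, lt, 50, "female", terminal_age = 100)$probability
  p110 <- lifetime_risk(tab, lt, 50, "female", terminal_age = 110)$probability
  expect_lt(abs(p110 - p100), 1e-4)
  expect_gte(p110, p100)
})

test_that("life tables given as death probabilities convert to hazards", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(sex = "female", age = 50:52, death_probability = c(0.01, 0.02, 0.5)),
    path
  )
  lt <- read_life_table(path)
  expect_equal(lt$death_hazard, -log(1 - c(0.01, 0.02, 0.5)))
  # out-of-support evaluation is a hard error, not an extrapolation
  hc <- life_table_hazard(lt, "female", terminal_age = 60)
  expect_error(hazard_at(hc, 45), "cover")
  expect_error(
    cumulative_incidence(hazard_curve(50, 0.01), hc, 45, 10),
    "cover"
  )
})
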