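test_that("well-formed registry files parse row for row", {
  path <- write_registry_csv(make_records(3))
  out <- read_registry(path)
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$rejections), 0)
  expect_equal(out$records$person_id, sprintf("P%03d", 1:3))
})

test_that("unparsable rows are rejected with a reason, never dropped silently", {
  recs <- make_records(3)
  recs$sex[2] <- ""
  path <- write_registry_csv(recs)
  out <- read_registry(path)
  expect_equal(nrow(out$records), 2)
  expect_equal(out$rejections$row, 2)
  expect_match(out$rejections$reason, "sex")
  # conservation: records in = parsed + rejected
  expect_equal(nrow(out$records) + nrow(out$rejections), 3)
})

test_that("a missing required column is a hard error naming the column", {
  recs <- make_records(2)
  recs$resident <- NULL
  path <- write_registry_csv(recs)
  expect_error(read_registry(path), "resident")
})

test_that("sex, flags and ICD-10 codes are normalised on read", {
  recs <- make_records(2)
  recs$sex <- c("F", "Male")
  recs$icd10 <- c("s72.0", "S 42.2")
  recs$surgical <- c("yes", "0")
  path <- write_registry_csv(recs)
  out <- read_registry(path)
  expect_equal(out$records$sex, c("female", "male"))
  expect_equal(out$records$icd10, c("S72.0", "S42.2"))
  expect_equal(out$records$surgical, c(TRUE, FALSE))
})

test_that("the case definition excludes under-age, pathological and non-resident records", {
  recs <- dplyr::bind_rows(
    make_records(age = 39), # below minimum age
    make_records(pathological = TRUE), # pathological
    make_records(resident = FALSE), # non-resident
    make_records(icd10 = "S52.5"), # wrong site for a hip query
    make_records(year = 2014), # outside window
    make_records(radiograph = FALSE), # clinical verification only
    make_records(age = 40), # boundary: exactly min_age is eligible
    make_records(age = 62) # high-energy trauma is not an exclusion
  )
  kept <- filter_eligible(recs, site_codes()$hip, min_age = 40, years = 2015:2017)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$age, c(40L, 62L))
  excl <- attr(kept, "exclusions")
  expect_equal(sum(excl$n) + nrow(kept), nrow(recs))
  expect_equal(excl$n[excl$reason == "pathological fracture"], 1L)
})

test_that("clinically-verified cases are retained only when the flag allows", {
  recs <- make_records(radiograph = FALSE)
  expect_equal(nrow(filter_eligible(recs, site_codes()$hip)), 0)
  expect_equal(nrow(filter_eligible(recs, site_codes()$hip, accept_clinical = TRUE)), 1)
})

test_that("an empty site set is a hard error", {
  expect_error(filter_eligible(make_records(1), character()), "site")
})

test_that("repeat admissions collapse to one record per person and site group", {
  same_person <- make_records(
    3,
    person_id = "P001", icd10 = c("S72.0", "S72.1", "S72.0"),
    year = c(2016L, 2015L, 2016L)
  )
  out <- deduplicate(same_person)
  expect_equal(nrow(out), 1)
  expect_equal(out$year, 2015L) # earliest event kept
  # different site groups in the same person are distinct events
  two_sites <- make_records(2, person_id = "P001", icd10 = c("S72.0", "S52.5"))
  expect_equal(nrow(deduplicate(two_sites)), 2)
  # idempotence on identical rows
  triple <- make_records(3, person_id = "P001")
  expect_equal(nrow(deduplicate(triple)), 1)
})

test_that("filtering then deduplication is idempotent", {
  sim <- simulate_registry(simulation_config(seed = 42))
  once <- deduplicate(filter_eligible(
    sim$registry, site_codes()$hip,
    years = 2015:2017, accept_clinical = TRUE
  ))
  twice <- deduplicate(filter_eligible(
    once, site_codes()$hip,
    years = 2015:2017, accept_clinical = TRUE
  ))
  attr(once, "exclusions") <- NULL
  attr(twice, "exclusions") <- NULL
  expect_identical(once, twice)
})

test_that("person-years sum annual populations over the study period", {
  pop <- tibble::tibble(
    sex = "female", age_lo = 40, age_hi = 45,
    year = 2015L, count = 1000
  )
  expect_equal(person_years(pop, "female", 40, 45, 2015), 1000)

  # under the period convention the printed population equals the
  # person-years of the whole study: annual thirds summed over three years
  hip <- fixture_tables()$hip_incidence
  pop3 <- tidyr::expand_grid(hip[, c("sex", "age_lo", "age_hi")], year = 2015:2017)
  pop3$count <- hip$person_years[match(
    paste(pop3$sex, pop3$age_lo), paste(hip$sex, hip$age_lo)
  )] / 3
  expect_equal(person_years(pop3, "female", 40, Inf, 2015:2017), 106880)
  expect_equal(person_years(pop3, "male", 40, Inf, 2015:2017), 77949)
  # two bands, two of three years
  expect_equal(
    person_years(pop3, "female", 40, 50, 2015:2016),
    (19142 + 17874) * 2 / 3
  )
})

test_that("a missing population cell is an error naming the cell, unless the nearest year is allowed", {
  pop <- tibble::tibble(
    sex = "male", age_lo = 50, age_hi = 55,
    year = c(2015L, 2016L), count = c(100, 110)
  )
  expect_error(person_years(pop, "male", 50, 55, 2015:2017), "2017")
  expect_equal(
    person_years(pop, "male", 50, 55, 2015:2017, fallback = "nearest"),
    100 + 110 + 110
  )
  expect_error(person_years(pop, "female", 50, 55, 2015), "tile")
})

test_that("age bands partition the age range and label as printed", {
  hip <- hip_age_bands()
  expect_equal(nrow(hip), 12)
  expect_equal(hip$band[c(1, 12)], c("40-44", "95+"))
  expect_true(all(hip$age_hi[-12] == hip$age_lo[-1]))
  expect_equal(
    assign_age_band(c(44, 45, 97, 39), hip),
    c("40-44", "45-49", "95+", NA)
  )
})
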