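Package: osteoepi
Title: Registry-Based Osteoporotic Fracture Epidemiology and Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for registry-based fracture epidemiology in settings
    with incomplete hospital ascertainment. Ingests, validates and
    deduplicates fracture case records coded by ICD-10 site; estimates age-
    and sex-specific incidence per 100,000 with exact (Garwood) Poisson
    confidence intervals; applies a prospective-capture uplift adjustment for
    cases that never reach hospital sources; imputes non-hip major
    osteoporotic fracture incidence from hip incidence via reference
    (Malmo-style) site ratios; projects national fracture counts onto
    population forecasts; and computes 10-year and remaining-lifetime
    fracture probabilities from piecewise-constant fracture and death hazards
    with competing mortality. A synthetic-registry generator with known
    ground truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
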