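---
title: "Registry-based fracture epidemiology: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry-based fracture epidemiology: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoepi)
```

# The problem

Fracture-risk tools of the FRAX family need two country-specific inputs:
age- and sex-specific hip fracture incidence, and age- and sex-specific
mortality. In much of the world neither a fracture register nor complete
hospital ascertainment exists, so incidence must be estimated from a
regional catchment survey — and corrected for the cases that never reach
hospital sources, a substantial fraction in health systems where surgical
capacity is limited and many hip-fracture patients stay at home. `osteoepi`
implements that estimation chain as a tested pipeline: registry cleaning,
capture-adjusted incidence with exact intervals, reference-ratio imputation
of non-hip fracture incidence, demographic projection of fracture counts,
and 10-year / lifetime fracture probabilities under competing mortality.

The package's defaults are calibrated to a three-year survey of a regional
catchment in Kazakhstan of about 165,000 people (roughly 350 hip fractures
over 2015--2017, with forearm and humerus fractures collected for
2015--2016); `fixture_tables()` carries the published marginal tables, and
the synthetic-data generator reproduces the survey's structure with known
ground truth.

# Registry cleaning

A registry file has one row per ascertained case: pseudonymous person id,
sex, age at fracture in completed years, calendar year, ICD-10 site code
(hip S72.0--S72.2, distal forearm S52.5--S52.6, proximal humerus S42.2),
admission status (admitted / formally refused / never presented to
hospital), and surgical, pathological, residence and radiograph flags.

Three conventions matter and are fixed here once:

* **Age bands are closed-open** `[lo, hi)` on age in completed years, so a
  band labelled "40--44" contains ages 40 to 44 inclusive. Hip uses 5-year
  bands with a terminal 95+ band; forearm/humerus use 10-year bands with a
  terminal 90+ band.
* **Person-years are annual populations summed over the study years**: a
  stratum of 6,000 people observed for three years contributes 18,000
  person-years. Published period tables print this sum directly as the
  "population" column, which is why a three-year catchment table shows
  populations roughly three times a single-year age pyramid.
* **Eligibility**: age at least 40, permanent resident, non-pathological
  fracture (pathological fractures from metastatic cancer or myeloma are
  contaminants for osteoporosis surveillance), radiographic confirmation,
  any trauma level. Prospectively ascertained hip cases examined at home
  are sometimes verified clinically only; `accept_clinical = TRUE` retains
  them, which is the convention for prospective-mode hip data. We default
  the flag to `FALSE` (radiograph required) because that is the safer
  retrospective rule; the prospective analyses in this package set it
  explicitly.

Deduplication collapses repeat admissions for the same fracture to one
record per (person, site group), keeping the earliest event year and
breaking year ties by input order. Laterality is not recorded in this kind
of register, so a contralateral second hip fracture within the window
cannot be distinguished from a readmission and is merged; this
undercounts slightly and is a known limitation of the source data, not a
tunable choice. Nothing is ever dropped silently: the reader returns
rejected rows with reasons, and the filter attaches an exclusion tally, so
record counts are conserved at every stage.

# Incidence and the capture adjustment

The crude rate of a stratum is `events / person_years * 1e5`. Confidence
intervals are exact (Garwood): the event-scale limits are gamma quantiles,
`qgamma(alpha/2, k)` and `qgamma(1 - alpha/2, k + 1)`, which invert the
Poisson tail probabilities, guarantee at-least-nominal coverage, and extend
naturally to the fractional event counts produced by the capture
adjustment. The test suite checks both the numerical inversion equivalence
and the empirical coverage (94--97% at the nominal 95%, exact intervals
being conservative).

The capture adjustment uses a two-phase design. Retrospective years count
only hospital-register cases; a prospective phase adds primary-care
ascertainment and so measures the shortfall. If registers yielded `r`
cases per year and the prospective year found `a` more, retrospective
years are uplifted by `(r + a) / r` — with the calibration survey's female
counts (65, 65 retrospective; 84 prospective, i.e. 19 additional) this is
84/65, a 29% uplift; the male uplift was 8%. The uplift is applied at the
sex-total level, not per age band: per-band prospective shortfalls are not
estimable from counts this small, so per-band adjusted rates inherit the
sex-level factor and are approximate by construction. Adjusted counts are
carried as fractions; rounding happens only in report output (half away
from zero to integers for rates, one decimal for ratios, matching how such
tables are printed).

# Imputing non-hip fracture incidence

Where only hip incidence is measured, the incidence of the other major
osteoporotic fractures is imputed by assuming the local age- and
sex-specific ratio of those fractures to hip fracture equals that of a
reference population (classically Malmö, Sweden):
`OMF_local = HF_local * OMF_ref / HF_ref`. The operation is linear in the
local hip rate and the reference target rate and inverse in the reference
hip rate, and imputing a table against itself is the identity — both are
tested as properties.

Predicted and observed rates are compared per stratum with a CI-exclusion
rule: a difference is flagged significant when the predicted rate falls
outside the exact 95% interval of the observed rate. On the bundled
predicted-versus-observed table this rule reproduces the published
significance marking in all sixteen strata. No reference incidence data
are bundled: the reference table is user-supplied, and the tests use a
synthetic one.

# Projection of fracture counts

Expected national counts apply the age- and sex-specific rates to a
projected population under the stable-rates assumption:
`sum(rate / 1e5 * population)` over bands, by sex and calendar year, with
percent change computed from unrounded totals against a base year.
Projection scope defaults to ages 50+ (the convention for hip-fracture
burden tables) while incidence tables start at 40; both are arguments.
The package deliberately bundles no demographic forecast data — the
projection table is an input.

# Fracture probability under competing mortality

Band rates are treated as annual hazards of *first* fracture (the registry
counts persons with at least one index fracture), piecewise constant on
the band intervals, with the terminal band's hazard held constant up to a
terminal age of 110. Mortality comes from a life table as annual hazards;
tables supplying annual death probabilities `q` are converted by
`h = -log(1 - q)`. For a person event-free at age `x`, the probability of
fracture before death within horizon `T`, with a proportional risk
multiplier `rr` (e.g. a prior-fracture profile), is

$$P = \int_0^T rr\,h_f(t)\; e^{-\int_0^t (rr\,h_f(u) + h_d(u))\,du}\,dt,$$

evaluated in closed form on every constant-hazard segment (segments split
at each knot of either curve and at the horizon) and summed — there is no
quadrature error, only the modelling choice of piecewise-constant hazards.
Lifetime risk integrates from the assessment age (default 50) to the
terminal age; with any realistic old-age mortality the integrand is
driven to zero well before 110, and the tests bound the terminal-age
sensitivity below 1e-4.

Design choices worth stating:

* **Piecewise-constant, not interpolated**, hazards between band
  boundaries: the simplest convention consistent with tabulated band
  rates. The convention is isolated in the `hazard_curve` type, so a
  smoothed alternative can be plugged in without touching the integrator.
* **No post-fracture excess mortality**: the engine implements the plain
  competing-hazard formulation. Full FRAX implementations model survival
  after fracture separately; with a single registry and a national life
  table that refinement is not identifiable, and the clinical-risk-factor
  coefficients of FRAX are proprietary, so risk profiles enter only
  through the `rr` multiplier.
* The closed-form segment sum is verified against an independent
  fine-grid trapezoid oracle to 1e-8, and the decomposition
  `P(0,T) = P(0,s) + S(s) P(s,T-s)` is checked numerically.

# The synthetic registry generator

`simulate_registry()` emulates the two-phase catchment survey, not a
generic population: stratum-level Poisson event counts (person-level
simulation adds nothing for these estimators and would slow the suite),
binomial hospital capture below 1, admission refusals, surgical treatment
among the admitted, duplicate readmission rows, pathological-fracture
contaminants, and primary-care ascertainment of the missed cases in
prospective years (flagged `not_presented`, half of them verified
clinically only). Defaults are the survey's conditions:

* population structure: the catchment's 5-year-band populations, one third
  of the published three-year person-years per calendar year;
* true hip incidence exponential in age, `rate(a) = rate50 * 2^((a-50)/d)`
  per 100,000: women `rate50 = 53.4`, doubling every 7 years; men
  `rate50 = 97.2`, doubling every 11 years — chosen to reproduce the
  survey's age pattern (female rates overtake male rates around age 70)
  and its expected adjusted counts (252 female, 141 male over three
  years);
* hip capture fractions 65/84 (women) and 1/1.08 (men), the values
  implied by the published 29% and 8% uplifts; forearm and humerus are
  taken as fully captured, flat-rate sites;
* refusal probability 82/348 and surgical probability 200/266, the
  survey's care-pathway proportions; duplicate probability 0.05 and a
  pathological contaminant rate of 2/100,000/year, plausible nuisance
  levels for a hospital register;
* Gompertz mortality `h(a) = alpha * exp(0.10 a)` with `alpha` solved so
  that life expectancy at 50 is 25 years (women) and 20 years (men) —
  a deliberately synthetic schedule of the right magnitude for the
  setting, not a copied national life table.

What the generator does *not* emulate: calendar-time trends, seasonality,
ethnic or urban/rural stratification, laterality, and any dependence of
capture on age. Passing recovery tests therefore demonstrate estimator
correctness under the stated ascertainment model, not robustness to those
real-data features.

With a fixed seed the output is byte-identical: all sampling happens in
one deterministic loop order over site, year, sex and band.

# Numerical and testing choices

* Rounding for report output is half away from zero (the convention of
  the printed tables); internal computation is never rounded.
* Missing population cells are hard errors naming the cell; an explicit
  `fallback = "nearest"` replicates the nearest year instead.
* Degenerate inputs fail loudly: zero person-years, an empty site set, a
  zero reference hip rate, hazard curves that do not cover the assessment
  age, and an uplift with zero retrospective cases are all errors rather
  than silent NAs.
* Problem sizes in the suite were chosen as the smallest that make the
  statistical assertions sharp: 2,000 replicates for interval coverage,
  300 for the capture fraction, 200 end-to-end pipeline replicates for
  parameter recovery (acceptance bands at 3 Monte-Carlo standard errors),
  and 8--10 random curves for each probability-engine property.

# Known limitations

* The capture adjustment assumes the prospective year's shortfall applies
  unchanged to the retrospective years and equally across age bands.
* Reference-ratio imputation inherits the reference population's fracture
  pattern; the bundled predicted-versus-observed table itself shows the
  assumption holding for men but underpredicting for women in several
  strata, which is precisely why the comparison operation exists.
* Probabilities use the plain competing-hazard model described above and
  a single proportional risk multiplier; they are not a substitute for a
  full clinical-risk-factor model.
* National projections extrapolate one region's rates to the country and
  hold them fixed over decades; both assumptions are stated, not tested.
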