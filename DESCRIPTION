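Package: cholinedb
Title: Compilation of a Choline Food-Composition Database and Estimation of
    Population Intakes from a Two-Day Weighted Dietary Survey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compile a nutrient (choline) database for a target food
    list by borrowing donor values with moisture and protein adjustment and
    FAO/INFOODS-style confidence codes, computing recipe-based composite foods
    with weight-change and retention factors, and applying quality-assurance
    checks; and to estimate population nutrient intakes from a two-day weighted
    24-hour-recall survey, including usual-intake estimation by residual
    shrinkage, design-based group summaries with grouped-jackknife standard
    errors, Adequate-Intake attainment, food-source rankings, and per-food-group
    survey-weighted regression models. Seeded synthetic-data generators emulate
    every input with known ground truth so the full pipeline is testable
    without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
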