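# cholinedb

Choline is an essential nutrient with Adequate Intake (AI) reference values
by age, sex and life stage, but many national food-composition databases
carry no choline values, so population intakes cannot be estimated directly
from dietary surveys. `cholinedb` implements the two computations needed to
close that gap for an AUSNUT-style food list and an NNPAS-style two-day
24-hour-recall survey:

1. **Database compilation.** Choline (and betaine) values for a target food
   list are *borrowed* from donor databases under FAO/INFOODS-style food
   matching, with a moisture (dry-matter) adjustment
   `v_target = v_donor × (100 − M_target) / (100 − M_donor)`
   (or a protein-ratio adjustment for protein-associated components), an
   A–D match confidence code, recipe-based composite foods computed as

   ```
   v = 100 · Σᵢ wᵢ (vᵢ/100) rᵢ  /  (c · Σᵢ wᵢ)
   ```

   (ingredient raw weights `wᵢ`, values `vᵢ`, retention factors `rᵢ`,
   weight-change/yield factor `c`), a flagged-zero policy for unmatched
   foods, and QA checks (rank ordering, per-group range checks, duplicate
   calculation, a seeded 10 % verification sample).

2. **Intake estimation.** Person-day intakes are summed from reported foods;
   usual (habitual) intakes are estimated by shrinking each person's
   observed mean toward a covariate prediction with
   `λ_d = σ²_between / (σ²_between + σ²_within / d)` for `d` recall days,
   the variance components coming from a one-way method-of-moments
   decomposition of regression residuals. Group summaries use survey
   weights, delete-a-group jackknife standard errors
   `SE = √(((R−1)/R) Σ_g (θ₍g₎ − θ)²)`, 95 % CIs as mean ± 2 SE, weighted
   quartile bounds, and AI attainment (share of persons with usual intake
   ≥ AI). Food-source rankings and per-food-group survey-weighted
   regressions (coefficient = mg choline per 100 g of the group, jackknife
   SEs, % variance explained) complete the pipeline.

Seeded generators (`generate_food_db()`, `generate_survey()`,
`generate_regression_data()`) emulate every input with known ground truth,
so the whole pipeline is testable without the restricted survey microdata.

## Worked example

```r
library(cholinedb)

fd <- generate_food_db(n_foods = 300, coverage_fraction = 0.9751, seed = 1)
db <- compile_database(fd$food, fd$donors, fd$matches, fd$recipes)
coverage_stats(db)$percent_of_total
#> [1] 97.67

sv    <- generate_survey(db, n_respondents = 2000,
                         sigma2_between = 400, sigma2_within = 1600, seed = 1)
daily <- daily_intake(sv$events, db, sv$design)
comp  <- fit_variance_components(daily, sv$respondents)
comp
#> Usual-intake variance components
#>   between-person: 378.28 (mg/day)^2
#>   within-person:  1671.33 (mg/day)^2
#>   shrinkage lambda(2 days): 0.3116

usual <- usual_intake(daily, comp, sv$respondents)
summ  <- build_group_summaries(usual, sv$respondents, default_ai_reference())
summ[summ$group_label == "Total", c("n", "mean", "se", "ci_low", "ci_high")]
#>      n   mean   se ci_low ci_high
#> 1 2000 263.06 0.67 261.72  264.41
```

The recovered components sit close to the generating values (400 and 1600
(mg/day)²; true λ₂ = 1/3), and the population mean tracks the generator's
stratum means (centred near 265 mg/day). `analysis/01_simulate.R` …
`analysis/06_models.R` run the same pipeline as a six-stage workflow,
writing each stage's table under `results/`; `run_all()` does the same in
one call with a reproducibility manifest.

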