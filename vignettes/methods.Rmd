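---
title: "Compiling a choline database and estimating population intakes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling a choline database and estimating population intakes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholinedb)
```

This vignette is the package's account of its methods: the borrowing and
recipe arithmetic behind the compiled database, the usual-intake model and
its estimator, the design-based summary statistics, and the design choices
made where more than one defensible option existed.

## 1. Compiling the nutrient database

### Value borrowing and adjustment

A target food without an analytical choline value receives one from a
*donor* food in another database. Because compositional context differs
between matched foods, the borrowed value is adjusted. Choline and betaine
are water-soluble, so the default adjustment is the dry-matter (moisture)
rescale

$$v_\text{target} = v_\text{donor} \cdot
  \frac{100 - M_\text{target}}{100 - M_\text{donor}},$$

with moistures in g/100 g strictly below 100 (a food that is all water has
no dry matter to scale by; the function refuses the degenerate case). The
protein-ratio adjustment $v_\text{donor} \cdot P_\text{target} /
P_\text{donor}$ is applied only when a match is explicitly marked
protein-associated, and falls back to the moisture adjustment when the
donor's protein is zero. The moisture adjustment is an exact involution —
adjusting to a target and back recovers the donor value — and that
round-trip is asserted property-style in the tests.

### Confidence codes

Match quality is graded A–D in the spirit of the FAO/INFOODS matching
guidance: A for an exact match (species, part/cut and processing all agree,
no adjustment), B when everything agrees but an adjustment was needed or
exactly one criterion was relaxed, C for two relaxations, D otherwise. The
published guidance is applied by judgement in practice; this package fixes
the rubric above so that the grade is a deterministic, monotone function of
the match flags — relaxing a criterion can never improve the code.

### Recipe composites

A composite food defined by a recipe with ingredient raw weights $w_i$,
values $v_i$ (mg/100 g), optional retention factors $r_i \in (0,1]$ and a
total weight-change (yield) factor $c > 0$ has

$$v = 100 \cdot \frac{\sum_i w_i \, (v_i/100) \, r_i}{c \sum_i w_i}.$$

The numerator is the nutrient mass entering the pot, the denominator the
cooked mass; the result is therefore mass-balanced by construction and
invariant to scaling all ingredient weights. Retention defaults to 1: the
survey database whose conventions we follow applies weight-change factors
in recipes, while per-ingredient retention (reported at 70–100 % for
choline) is offered as an optional extension. Nested recipes are resolved
in topological order and cycles are hard errors naming the cycle.

### Zero policy, QA and coverage

Foods for which no value can be found are recorded as 0 mg/100 g with
`source = "unmatched_zero"` and a distinguishing flag, because downstream
intake arithmetic needs a number but a policy zero must never be confused
with an analytical zero. Coverage statistics count only genuine values.
QA mirrors standard compilation practice: rank ordering, per-2-digit-group
range checks (bounds are configuration, not constants), recomputation of
every recipe as a duplicate-calculation check, and a seeded 10 % random
verification sample drawn without replacement.

## 2. Usual intake from two recall days

A single 24-hour recall is a noisy measure of habitual intake. With up to
two days per person, person-day intakes are modelled as

$$y_{ij} = \beta' z_i + u_i + e_{ij}, \qquad
  u_i \sim (0, \sigma^2_b), \quad e_{ij} \sim (0, \sigma^2_w),$$

and the usual intake of person $i$ with $d_i$ recall days is the shrinkage
estimate

$$\hat{y}_i = \beta' z_i + \lambda_{d_i} (\bar{y}_i - \beta' z_i), \qquad
  \lambda_d = \frac{\sigma^2_b}{\sigma^2_b + \sigma^2_w / d}.$$

Estimation is deliberately simple and transparent: an ordinary
least-squares fit of all person-days on the covariates, then a one-way
method-of-moments decomposition of the residuals (pooled within-person sum
of squares for $\sigma^2_w$; the between-person mean square with the
unbalanced-design group-size correction $n_0$ for $\sigma^2_b$, truncated
at zero). On balanced data this reduces to the classical one-way ANOVA
estimator, which the tests verify against `aov()` and, as an independent
cross-check, against an REML mixed-model fit.

Choices made here, and why:

* **Covariates.** The default model crosses age band with sex — the
  survey's reporting strata. An additive model would leave stratum-level
  mean structure in the residuals, where the between-person component would
  absorb it and $\lambda$ would be biased upward; the crossed model keeps
  the person effect a within-stratum deviation. The formula is an argument,
  so any covariate set can be supplied.
* **Unbalanced days.** Persons with one day are shrunken with $\lambda_1$;
  no second day is imputed.
* **No transformation by default.** Choline intake distributions are only
  mildly skewed, and an untransformed analysis keeps every quantity in
  mg/day. A `transform = "log"` option (fit on `log(y + 1)`, naive
  exponential back-transform) exists as a documented extension.
* **Zero days are real.** Choline is consumed daily; a designed person-day
  with no events is a true 0 mg/day, not missing, and no episodic two-part
  model is used.

Shrinkage guarantees every usual intake lies between the covariate
prediction and the observed person mean, and that the usual-intake
distribution is no more dispersed than the person means — both asserted as
properties in the tests.

## 3. Design-based summaries

Survey weights enter every population statement. Group summaries report the
unweighted $n$, the population equivalent $\sum_i w_i$, the weighted mean,
and a delete-a-group jackknife standard error

$$\widehat{SE}(\hat\theta) = \sqrt{\frac{R-1}{R}
  \sum_{g=1}^{R} (\hat\theta_{(g)} - \hat\theta)^2},$$

where $\hat\theta_{(g)}$ recomputes the statistic under replicate-weight
column $g$. With leave-one-out replicate weights this reproduces the
textbook delete-1 jackknife exactly, which the tests check by brute-force
enumeration. A replicate under which a subgroup statistic is undefined
(every member of a small group deleted) contributes zero deviation; an
all-zero replicate column raises a warning but is still used.

Confidence intervals are mean ± 2 SE — the reporting convention of the
survey tables this output mirrors, confirmed by recomputing published rows
exactly; a 1.96 multiplier is available by argument. Weighted quartile
bounds are the lowest values whose cumulative normalised weight reaches
0, ¼, ½, ¾, 1, giving four contiguous population quartile intervals.

AI attainment compares each person's usual intake with their Adequate
Intake (matched on age band, sex and life stage; pregnancy and lactation
rows take precedence over plain female bands). The percentage uses
unweighted counts — that convention reproduces the published example rows
exactly (e.g. 311 of 464 → 67.03 %) — while the population equivalent of
attainers carries the weighted companion figure. Means, SEs, CIs, quartile
bounds and percentages are rounded to 2 decimals at report time; population
equivalents are left unrounded.

## 4. Food sources and per-group models

Source rankings use day-1 reported intakes (not usual intakes): a ranking
of consumption days should reflect what was actually eaten on a day, and
the second recall day is not available for everyone. Every event belongs to
exactly one 3-digit food group (2- and 5-digit levels by argument), so
attributed milligrams sum to total milligrams exactly; shares are weighted,
consumer counts unweighted, ties in share break by ascending group code.

Each food-group regression models total daily intake (usual intake by
default; the day-average is one argument away) on the group's grams/day
divided by 100 — so the coefficient reads "mg choline per 100 g of the
group" — plus energy, physical-activity level (1–5), sex, age and education
level (1–5). Point estimates are weighted least squares; SEs are the
grouped jackknife applied coefficient-wise (one refit per replicate
column); p-values use a t reference with $\max(R - p, 1)$ degrees of
freedom; $R^2$ is weighted. Models are ranked by percent variance
explained, with infant-food groups excludable since the surveyed ages make
them degenerate.

## 5. What the synthetic data emulates — and what it does not

The generators produce every input the pipeline reads, in miniature:

* a food list over a nested 2/3/5-digit hierarchy (about 10 two-digit
  majors, 24 three-digit groups) with log-normal within-group choline
  densities, donors whose values recover the target truth exactly under the
  moisture adjustment, match flags, recipes with known closed-form values,
  and an exactly controlled fraction of valued foods;
* a survey of respondents over sex × age strata whose true means follow the
  published reporting rows in shape (185–310 mg/day, centred near
  265 mg/day), person effects and day deviations with configurable
  $\sigma^2_b = 400$ and $\sigma^2_w = 1600$ (mg/day)² by default, a
  configurable day-2 subset (85 % by default), log-normal sampling weights,
  delete-a-group replicate weights ($R = 30$), and intake events
  constructed so person-day food totals reproduce the simulated intakes to
  numerical precision.

Default problem sizes — 2000 respondents for parameter recovery, 3000
persons × 100 replications for jackknife calibration, a 5740-food list for
coverage — were chosen as the smallest scales at which the moment
estimators are comfortably inside their stated recovery bands.

What passing tests on these data show is that the *estimators recover known
truth under the model's own assumptions* at realistic scale. What they do
not show: robustness to reporting error and selective misreporting, to
skewed intake distributions (the generator is Gaussian on the natural
scale), to informative weighting, or to the matching judgement embedded in
a real compilation — those require real microdata and local food-supply
knowledge.

## 6. Numerical conventions and limitations

* All adjusted and computed values are stored unrounded; rounding (2
  decimals) happens only in report output.
* Randomness is confined to explicitly seeded generators that restore the
  caller's RNG stream; identical seeds give byte-identical outputs.
* Quartile bounds use a `1e-12` slack on cumulative-weight comparisons to
  keep exact quarter boundaries stable under floating-point summation.
* Negative moment estimates of variance components truncate at zero; when
  both components are zero, $\lambda$ is defined as 1 (nothing to shrink).
* The moment estimator of $\sigma^2_b$ has substantial sampling variance at
  survey sizes of a few hundred; recovery statements in the tests are made
  at $n = 2000$.
* The matcher does not attempt automated text-similarity food matching:
  candidate pairs and their sameness flags are inputs, because real
  compilations rest on expert judgement that should not be hidden inside a
  heuristic.
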