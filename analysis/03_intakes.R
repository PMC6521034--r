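#!/usr/bin/env Rscript
# Stage 3: person-day intakes from the reported events, variance-component
# estimation, and usual (habitual) intakes by residual shrinkage.

suppressMessages(library(cholinedb))

db <- read_nutrient_db("results/compiled_db.csv")
respondents <- readr::read_csv("results/inputs/respondents.csv",
                               show_col_types = FALSE)
events <- readr::read_csv("results/inputs/events.csv",
                          show_col_types = FALSE)
design <- readr::read_csv("results/inputs/design.csv",
                          show_col_types = FALSE)

daily <- daily_intake(events, db, design)
comp <- fit_variance_components(daily, respondents)
usual <- usual_intake(daily, comp, respondents)
readr::write_csv(usual, "results/usual_intakes.csv")

print(comp)
cat(sprintf("usual intakes for %d respondents (%d with two days); variance of person means %.0f, of usual intakes %.0f\n",
            nrow(usual), sum(usual$n_days == 2),
            stats::var(usual$person_mean), stats::var(usual$usual)))
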