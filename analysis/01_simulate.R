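#!/usr/bin/env Rscript
# Stage 1: generate the full synthetic input bundle — target food list,
# donor table, candidate matches, recipe file, AI reference and a weighted
# two-day survey with known ground truth — under one seed.

suppressMessages(library(cholinedb))

SEED <- 1L
dir.create("results", showWarnings = FALSE)

fooddb <- generate_food_db(n_foods = 5740, coverage_fraction = 0.9751,
                           n_recipes = 20, seed = SEED)
db <- compile_database(fooddb$food, fooddb$donors, fooddb$matches,
                       fooddb$recipes)
survey <- generate_survey(db, n_respondents = 2000, sigma2_between = 400,
                          sigma2_within = 1600, seed = SEED + 1L)
write_input_bundle(fooddb, survey, "results/inputs")

cat(sprintf("wrote input bundle: %d foods (%d donors, %d recipes), %d respondents, %d intake events\n",
            nrow(fooddb$food), nrow(fooddb$donors), length(fooddb$recipes),
            nrow(survey$respondents), nrow(survey$events)))
cat(sprintf("ground truth: sigma2_between %.0f, sigma2_within %.0f, lambda(2) %.4f\n",
            survey$truth$sigma2_between, survey$truth$sigma2_within,
            survey$truth$lambda_2))
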