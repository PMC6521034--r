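# Seeded generators for every pipeline input: food/donor tables, recipes,
# AI references and a weighted two-day survey with known ground truth
# (variance components, stratum means, food-group effects), so every stage
# is testable without restricted microdata.

# Miniature food-group hierarchy: a subset of 2-digit majors, each with a
# few 3-digit subgroups, and a log-scale typical choline density. Shapes
# follow the AUSNUT-style nested coding; names are generic.
.synthetic_groups <- function() {
  tibble::tribble(
    ~group2, ~n_sub, ~meanlog, ~label,
    "11",    2,      1.0,      "beverages",
    "12",    3,      2.8,      "cereals and grains",
    "13",    3,      3.2,      "cereal-based dishes",
    "16",    2,      2.0,      "fruit",
    "19",    3,      3.0,      "milk products",
    "20",    3,      4.2,      "meat, poultry and game dishes",
    "22",    2,      3.9,      "fish and seafood",
    "24",    3,      2.7,      "vegetables",
    "28",    1,      5.5,      "eggs",
    "30",    2,      2.2,      "fats and oils")
}

#' Generate a synthetic food list with donors, matches and recipes
#'
#' Builds a miniature AUSNUT-like target food list over a nested 2/3/5-digit
#' group hierarchy with log-normal within-group choline densities, a donor
#' table whose values reproduce the target truth after moisture adjustment,
#' candidate match pairs, a handful of recipes over valued ingredients, and
#' the list of foods left unmatched so that exactly
#' `round(coverage_fraction * n_foods)` foods end up valued.
#'
#' @param n_foods Number of target foods.
#' @param coverage_fraction Fraction of foods that receive a genuine value.
#' @param n_recipes Number of composite (recipe) foods among the valued.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List: `food`, `donors`, `matches`, `recipes`, `unmatched_ids`,
#'   `truth` (true per-food choline values, recipe closed forms, coverage).
#' @export
generate_food_db <- function(n_foods = 500, coverage_fraction = 0.9751,
                             n_recipes = 10, seed = 1L) {
  .with_seed(seed, {
    groups <- .synthetic_groups()
    g3 <- unlist(lapply(seq_len(nrow(groups)), function(i) {
      paste0(groups$group2[i], seq_len(groups$n_sub[i]))
    }))
    g3_meanlog <- rep(groups$meanlog, groups$n_sub)
    pick <- sample(length(g3), n_foods, replace = TRUE)
    suffix <- sprintf("%05d", sample(0:99999, n_foods))
    food_id <- paste0(g3[pick], suffix)
    while (anyDuplicated(food_id)) {
      dup <- duplicated(food_id)
      food_id[dup] <- paste0(g3[pick][dup],
                             sprintf("%05d", sample(0:99999, sum(dup))))
    }
    moisture <- round(runif(n_foods, 5, 95), 1)
    protein <- round(rgamma(n_foods, shape = 2, scale = 5), 1)
    energy <- round(runif(n_foods, 100, 2500))
    true_choline <- round(rlnorm(n_foods, g3_meanlog[pick], 0.5), 3)
    true_betaine <- round(rlnorm(n_foods, g3_meanlog[pick] - 1.5, 0.6), 3)

    n_valued <- round(coverage_fraction * n_foods)
    valued_idx <- sort(sample(n_foods, n_valued))
    n_recipes <- min(n_recipes, max(0, n_valued - 20))
    recipe_idx <- sample(valued_idx, n_recipes)
    rest <- setdiff(valued_idx, recipe_idx)
    analytical_idx <- sample(rest, max(1, round(0.05 * length(rest))))
    borrowed_idx <- setdiff(rest, analytical_idx)

    food <- tibble::tibble(
      food_id = food_id,
      name = paste("synthetic food", food_id),
      moisture = moisture, protein = protein, energy = energy,
      choline = ifelse(seq_len(n_foods) %in% analytical_idx,
                       true_choline, NA_real_),
      betaine = ifelse(seq_len(n_foods) %in% analytical_idx,
                       true_betaine, NA_real_))
    food <- .add_group_codes(food)
    food$source <- ifelse(!is.na(food$choline), "analytical", NA_character_)
    food$confidence <- NA_character_
    food$unmatched_zero <- FALSE
    food$donor_id <- NA_character_
    food <- food[, c("food_id", "name", "group2", "group3", "group5",
                     "moisture", "protein", "energy", "choline", "betaine",
                     "source", "confidence", "unmatched_zero", "donor_id")]

    # donors: composition differs; the donor value is chosen so that the
    # moisture adjustment recovers the target's true value exactly
    donor_moist <- pmin(99, pmax(0, moisture[borrowed_idx] +
                                   round(runif(length(borrowed_idx), -15, 15), 1)))
    donor_choline <- true_choline[borrowed_idx] *
      (100 - donor_moist) / (100 - moisture[borrowed_idx])
    has_bet <- runif(length(borrowed_idx)) < 0.7
    donor_betaine <- ifelse(has_bet, true_betaine[borrowed_idx] *
                              (100 - donor_moist) /
                              (100 - moisture[borrowed_idx]), NA_real_)
    donors <- tibble::tibble(
      donor_id = sprintf("D%05d", seq_along(borrowed_idx)),
      donor_name = paste("donor for", food_id[borrowed_idx]),
      moisture = donor_moist,
      protein = pmax(0.1, protein[borrowed_idx] +
                       round(runif(length(borrowed_idx), -2, 2), 1)),
      choline = donor_choline,
      betaine = donor_betaine,
      donor_source = sample(c("donor database", "literature study"),
                            length(borrowed_idx), replace = TRUE))
    matches <- tibble::tibble(
      target_id = food_id[borrowed_idx],
      donor_id = donors$donor_id,
      adjustment = "moisture",
      same_species = runif(length(borrowed_idx)) < 0.8,
      same_part_or_cut = runif(length(borrowed_idx)) < 0.8,
      same_processing = runif(length(borrowed_idx)) < 0.9)

    # recipes draw 2-4 non-recipe valued ingredients each
    ingredient_pool <- setdiff(valued_idx, recipe_idx)
    recipes <- list()
    recipe_truth <- numeric(0)
    for (ri in recipe_idx) {
      k <- sample(2:4, 1)
      ing <- sample(ingredient_pool, k)
      w <- round(runif(k, 20, 200))
      ret <- round(runif(k, 0.7, 1), 2)
      wcf <- round(runif(1, 0.7, 1.1), 2)
      recipes[[food_id[ri]]] <- recipe_spec(
        recipe_id = food_id[ri],
        ingredients = tibble::tibble(food_id = food_id[ing], raw_weight = w,
                                     retention = ret),
        weight_change_factor = wcf)
      recipe_truth[food_id[ri]] <-
        100 * sum(w * true_choline[ing] / 100 * ret) / (wcf * sum(w))
      true_choline[ri] <- recipe_truth[food_id[ri]]
    }
    unmatched_ids <- food_id[-valued_idx]
    truth <- list(coverage_fraction = coverage_fraction,
                  n_valued = n_valued,
                  true_choline = stats::setNames(true_choline, food_id),
                  recipe_values = recipe_truth,
                  group_labels = stats::setNames(groups$label, groups$group2))
    list(food = food, donors = donors, matches = matches, recipes = recipes,
         unmatched_ids = unmatched_ids, truth = truth)
  })
}

#' Adequate Intake reference values by age, sex and life stage
#'
#' The Australian AI bands for choline (mg/day) used for attainment
#' reporting: 200 (2-3 y), 250 (4-8 y), 375 (9-13 y), 550/400 (male/female
#' 14-18 y), 550/425 (male/female adults), and 415/440 (pregnant 14-18 /
#' 19-50 y) and 550 (lactating).
#'
#' @return AI reference tibble ([read_ai_reference()] layout).
#' @export
default_ai_reference <- function() {
  validate_ai_reference(tibble::tribble(
    ~group_label,            ~sex,     ~age_min, ~age_max, ~life_stage, ~ai,
    "2-3 years",             "any",    2,  3,  "none",      200,
    "4-8 years",             "any",    4,  8,  "none",      250,
    "9-13 years",            "any",    9,  13, "none",      375,
    "Male 14-18 years",      "male",   14, 18, "none",      550,
    "Female 14-18 years",    "female", 14, 18, "none",      400,
    "Male 19-85 years",      "male",   19, 85, "none",      550,
    "Female 19-85 years",    "female", 19, 85, "none",      425,
    "Pregnant 14-18 years",  "female", 14, 18, "pregnant",  415,
    "Pregnant 19-50 years",  "female", 19, 50, "pregnant",  440,
    "Lactating 14-18 years", "female", 14, 18, "lactating", 550,
    "Lactating 19-50 years", "female", 19, 50, "lactating", 550))
}

# Default survey strata: sex x age band with sampling proportions and true
# mean intakes (mg/day) shaped like the national survey's reporting rows,
# centred near 265 mg/day.
.default_strata <- function() {
  tibble::tribble(
    ~sex,     ~age_min, ~age_max, ~prop,  ~true_mean,
    "any",    2,        3,        0.038,  185,
    "any",    4,        8,        0.065,  203,
    "male",   9,        13,       0.032,  244,
    "male",   14,       18,       0.033,  275,
    "male",   19,       64,       0.277,  310,
    "male",   65,       85,       0.075,  281,
    "female", 9,        13,       0.033,  228,
    "female", 14,       18,       0.030,  229,
    "female", 19,       64,       0.300,  248,
    "female", 65,       85,       0.098,  249)
}

#' Generate a synthetic weighted two-day dietary survey
#'
#' Simulates respondents over sex/age strata with known true mean intakes,
#' person effects `u_i ~ N(0, sigma2_between)` and day deviations
#' `e_ij ~ N(0, sigma2_within)` (intakes floored at 0), sampling weights,
#' delete-a-group replicate weights, and intake events constructed so each
#' person-day's food totals reproduce the simulated intake exactly.
#'
#' @param db Compiled nutrient database supplying the foods events draw on.
#' @param n_respondents Number of respondents.
#' @param sigma2_between,sigma2_within Variance components, (mg/day)^2.
#' @param day2_fraction Fraction of respondents with a second recall day.
#' @param n_replicates Number R of replicate-weight columns.
#' @param strata Stratum definition tibble (`sex`, `age_min`, `age_max`,
#'   `prop`, `true_mean`).
#' @param pregnant_fraction,lactating_fraction Fractions of women aged
#'   19-50 assigned those life stages (their intake keeps the stratum mean).
#' @param seed Integer seed.
#' @return List: `respondents` (with `repw_*` columns), `events`, `design`
#'   (person-day frame) and `truth` (components, `lambda_2`, strata, the
#'   simulated person-day intakes).
#' @export
generate_survey <- function(db, n_respondents = 2000,
                            sigma2_between = 400, sigma2_within = 1600,
                            day2_fraction = 0.85, n_replicates = 30,
                            strata = .default_strata(),
                            pregnant_fraction = 0.02,
                            lactating_fraction = 0.02,
                            seed = 1L) {
  .with_seed(seed, {
    n <- n_respondents
    st <- sample(nrow(strata), n, replace = TRUE,
                 prob = strata$prop / sum(strata$prop))
    age <- mapply(function(a, b) sample(a:b, 1),
                  strata$age_min[st], strata$age_max[st])
    sex <- ifelse(strata$sex[st] == "any",
                  sample(c("male", "female"), n, replace = TRUE),
                  strata$sex[st])
    life_stage <- rep("none", n)
    eligible <- which(sex == "female" & age >= 19 & age <= 50)
    if (length(eligible) > 2) {
      r <- runif(length(eligible))
      life_stage[eligible[r < pregnant_fraction]] <- "pregnant"
      life_stage[eligible[r >= pregnant_fraction &
                            r < pregnant_fraction + lactating_fraction]] <-
        "lactating"
    }
    weight <- rlnorm(n, meanlog = log(1000), sdlog = 0.4)
    rep_group <- sample(n_replicates, n, replace = TRUE)
    repw <- vapply(seq_len(n_replicates), function(g) {
      ifelse(rep_group == g, 0, weight * n_replicates / (n_replicates - 1))
    }, numeric(n))
    colnames(repw) <- paste0("repw_", seq_len(n_replicates))
    respondents <- tibble::tibble(
      resp_id = sprintf("R%05d", seq_len(n)),
      age = as.integer(age), sex = sex, life_stage = life_stage,
      weight = weight,
      education_level = sample(1:5, n, replace = TRUE),
      activity_level = sample(1:5, n, replace = TRUE),
      energy = pmax(1500, rnorm(n, 8700, 2000)))
    respondents <- dplyr::bind_cols(respondents, tibble::as_tibble(repw))

    mu <- strata$true_mean[st]
    u <- rnorm(n, 0, sqrt(sigma2_between))
    has_day2 <- runif(n) < day2_fraction
    design <- tibble::tibble(
      resp_id = c(respondents$resp_id, respondents$resp_id[has_day2]),
      day = c(rep(1L, n), rep(2L, sum(has_day2))))
    design <- dplyr::arrange(design, .data$resp_id, .data$day)
    pid <- match(design$resp_id, respondents$resp_id)
    intake <- pmax(0, mu[pid] + u[pid] +
                     rnorm(nrow(design), 0, sqrt(sigma2_within)))

    # foods with a positive value carry the events; popularity weights make
    # some groups dominate, as real food-source rankings do
    pool <- which(!is.na(db$choline) & db$choline > 0)
    popularity <- rlnorm(length(pool), 0, 1.2) *
      db$choline[pool] / mean(db$choline[pool])
    f_list <- vector("list", nrow(design))
    g_list <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      if (intake[i] <= 0) next
      k <- sample(1:4, 1)
      f <- pool[sample(length(pool), k, prob = popularity)]
      share <- runif(k)
      share <- share / sum(share)
      f_list[[i]] <- f
      g_list[[i]] <- share * intake[i] / (db$choline[f] / 100)
    }
    n_ev <- lengths(f_list)
    events <- tibble::tibble(resp_id = rep(design$resp_id, n_ev),
                             day = rep(design$day, n_ev),
                             food_id = db$food_id[unlist(f_list)],
                             grams = unlist(g_list))
    lambda2 <- sigma2_between / (sigma2_between + sigma2_within / 2)
    truth <- list(sigma2_between = sigma2_between,
                  sigma2_within = sigma2_within,
                  lambda_2 = lambda2, strata = strata,
                  stratum_index = st,
                  person_effect = u,
                  intake = tibble::tibble(resp_id = design$resp_id,
                                          day = design$day, intake = intake))
    list(respondents = respondents, events = events, design = design,
         truth = truth)
  })
}

#' Generate regression data with a known food-group effect
#'
#' Simulates per-person totals `total = intercept + beta * (grams / 100) +
#' covariate effects + noise` with survey-style weights and delete-a-group
#' replicate weights, for calibrating the food-group regression and its
#' jackknife standard errors.
#'
#' @param n Number of persons.
#' @param beta True coefficient, mg choline per 100 g of the group.
#' @param sigma_noise Residual SD of the total (mg/day); 0 gives a
#'   noiseless design with exact recovery.
#' @param n_replicates Number of replicate-weight columns.
#' @param seed Integer seed.
#' @return List: `data` (tibble with `total`, `group_grams` and covariates),
#'   `weights`, `replicate_weights`, `truth` (all generating coefficients).
#' @export
generate_regression_data <- function(n = 3000, beta = 48.2,
                                     sigma_noise = 40, n_replicates = 30,
                                     seed = 1L) {
  .with_seed(seed, {
    group_grams <- rgamma(n, shape = 1.2, scale = 80)
    group_grams[runif(n) < 0.3] <- 0     # non-consumers of the group
    energy <- rnorm(n, 8700, 2000)
    activity_level <- sample(1:5, n, replace = TRUE)
    education_level <- sample(1:5, n, replace = TRUE)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    age <- sample(2:85, n, replace = TRUE)
    truth <- list(intercept = 120, beta = beta, energy = 0.01,
                  activity = 1.5, sex_male = 20, age = 0.3, education = -2)
    total <- truth$intercept + beta * group_grams / 100 +
      truth$energy * (energy - 8700) + truth$activity * activity_level +
      truth$sex_male * (sex == "male") + truth$age * age +
      truth$education * education_level +
      rnorm(n, 0, sigma_noise)
    weight <- rlnorm(n, log(1000), 0.4)
    rep_group <- sample(n_replicates, n, replace = TRUE)
    rw <- vapply(seq_len(n_replicates), function(g) {
      ifelse(rep_group == g, 0, weight * n_replicates / (n_replicates - 1))
    }, numeric(n))
    colnames(rw) <- paste0("repw_", seq_len(n_replicates))
    list(data = tibble::tibble(total = total, group_grams = group_grams,
                               energy = energy - 8700,
                               activity_level = activity_level,
                               education_level = education_level,
                               sex = sex, age = age),
         weights = weight, replicate_weights = rw, truth = truth)
  })
}

#' Write a synthetic input bundle to CSV files
#'
#' Writes the food table, donor table, candidate matches, recipe file
#' (long form), AI reference, respondents, events and a ground-truth
#' sidecar (YAML) into a directory.
#'
#' @param fooddb Output of [generate_food_db()].
#' @param survey Output of [generate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(fooddb, survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) readr::write_csv(df, file.path(dir, f), na = "",
                                        progress = FALSE)
  w(fooddb$food[, c("food_id", "name", "moisture", "protein", "energy",
                    "choline", "betaine")], "food_table.csv")
  w(fooddb$donors, "donor_table.csv")
  w(fooddb$matches, "matches.csv")
  recipe_rows <- purrr::map_dfr(fooddb$recipes, function(r) {
    tibble::tibble(recipe_id = r$recipe_id,
                   ingredient_id = r$ingredients$food_id,
                   raw_weight = r$ingredients$raw_weight,
                   weight_change_factor = r$weight_change_factor,
                   retention = r$ingredients$retention)
  })
  w(recipe_rows, "recipes.csv")
  w(default_ai_reference(), "ai_reference.csv")
  w(survey$respondents, "respondents.csv")
  w(survey$events, "events.csv")
  w(survey$design, "design.csv")
  truth <- list(coverage_fraction = fooddb$truth$coverage_fraction,
                n_valued = fooddb$truth$n_valued,
                sigma2_between = survey$truth$sigma2_between,
                sigma2_within = survey$truth$sigma2_within,
                lambda_2 = survey$truth$lambda_2)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
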