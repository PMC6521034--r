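test_that("moisture adjustment rescales to the target dry-matter fraction", {
  expect_equal(moisture_adjust(100, 60, 60), 100)  # identity
  expect_equal(moisture_adjust(100, 60, 80), 50)   # 100 * 20/40
  expect_equal(moisture_adjust(0, 30, 70), 0)      # zero preserved
  expect_error(moisture_adjust(10, 100, 50), class = "cholinedb_domain_error")
  expect_error(moisture_adjust(-1, 50, 50), class = "cholinedb_domain_error")
})

test_that("moisture adjustment round-trips (dry-matter conservation)", {
  set.seed(11)
  for (i in 1:50) {
    v <- runif(1, 0, 500)
    a <- runif(1, 0, 99)
    b <- runif(1, 0, 99)
    expect_equal(moisture_adjust(moisture_adjust(v, a, b), b, a), v)
  }
})

test_that("protein adjustment is a proportional rescale", {
  expect_equal(protein_adjust(80, 20, 10), 40)
  expect_equal(protein_adjust(80, 15, 15), 80)
  expect_error(protein_adjust(80, 0, 10),
               class = "cholinedb_adjustment_error")
})

test_that("confidence rubric is monotone in the match flags", {
  expect_equal(assign_confidence(TRUE, TRUE, TRUE, FALSE), "A")
  expect_equal(assign_confidence(TRUE, TRUE, TRUE, TRUE), "B")
  expect_equal(assign_confidence(FALSE, FALSE, FALSE, TRUE), "D")
  # relaxing any sameness flag never improves the code
  for (s in c(TRUE, FALSE)) for (p in c(TRUE, FALSE)) {
    for (k in c(TRUE, FALSE)) for (a in c(TRUE, FALSE)) {
      base <- assign_confidence(s, p, k, a)
      for (flip in 1:3) {
        flags <- c(s, p, k)
        if (!flags[flip]) next
        flags[flip] <- FALSE
        relaxed <- assign_confidence(flags[1], flags[2], flags[3], a)
        expect_gte(match(relaxed, LETTERS), match(base, LETTERS))
      }
    }
  }
})

test_that("borrowing applies the policy adjustment and grades the match", {
  target <- list(food_id = "13102031", moisture = 80, protein = 3, energy = 300)
  donor_same <- list(donor_id = "D1", moisture = 80, protein = 3,
                     choline = 40, betaine = 2, energy = 300)
  res <- borrow_value(target, donor_same, list(adjustment = "moisture"))
  expect_equal(res$adjusted_choline, 40)
  expect_equal(res$adjustment, "none")
  expect_equal(res$confidence, "A")
  donor_dry <- list(donor_id = "D2", moisture = 60, protein = 3,
                    choline = 100, betaine = NA_real_, energy = 300)
  res2 <- borrow_value(target, donor_dry, list(adjustment = "moisture"))
  expect_equal(res2$adjusted_choline, moisture_adjust(100, 60, 80))
  expect_equal(res2$confidence, "B")
  expect_true(is.na(res2$adjusted_betaine))  # absence propagates
  # energy-similarity tolerance rejects implausible matches
  expect_error(
    borrow_value(list(food_id = "13102031", moisture = 80, protein = 3,
                      energy = 900),
                 donor_same, list(energy_ratio_tol = 0.25)),
    class = "cholinedb_match_error")
})

test_that("recipe computation matches the closed form", {
  db <- tibble::tibble(food_id = c("28101001", "13102031"),
                       choline = c(100, 0), betaine = c(NA_real_, NA_real_))
  r <- recipe_spec("20205007",
                   tibble::tibble(food_id = c("28101001", "13102031"),
                                  raw_weight = c(50, 50)),
                   weight_change_factor = 0.8)
  expect_equal(compute_recipe(r, db), 62.5)  # 50 mg nutrient in 80 g cooked
  ident <- recipe_spec("20205008",
                       tibble::tibble(food_id = "28101001", raw_weight = 120),
                       weight_change_factor = 1)
  expect_equal(compute_recipe(ident, db), 100)
  ident$ingredients$retention <- 0.7
  expect_equal(compute_recipe(ident, db), 70)  # linear in retention
})

test_that("recipe results are mass-balanced and weight-scale invariant", {
  set.seed(3)
  fd <- generate_food_db(60, 1, 0, seed = 3)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    ing <- tibble::tibble(food_id = sample(db$food_id, k),
                          raw_weight = runif(k, 10, 300),
                          retention = runif(k, 0.7, 1))
    wcf <- runif(1, 0.7, 1.2)
    r <- recipe_spec("99999999", ing, wcf)
    v <- compute_recipe(r, db)
    cooked_mass <- wcf * sum(ing$raw_weight)
    chol <- db$choline[match(ing$food_id, db$food_id)]
    expect_equal(v * cooked_mass / 100,
                 sum(ing$raw_weight * chol / 100 * ing$retention))
    # doubling all ingredient weights leaves the per-100 g value unchanged
    r2 <- recipe_spec("99999999",
                      dplyr::mutate(ing, raw_weight = raw_weight * 2), wcf)
    expect_equal(compute_recipe(r2, db), v)
  }
})

test_that("nested recipes resolve in dependency order; cycles are errors", {
  db <- tiny_db()
  db <- dplyr::bind_rows(db, db[1, ])
  db$food_id[4] <- "20205099"
  db$choline[4] <- NA
  nested <- list(
    recipe_spec("20205099",
                tibble::tibble(food_id = "20205007", raw_weight = 100),
                1),
    recipe_spec("20205007",
                tibble::tibble(food_id = c("28101001", "13102031"),
                               raw_weight = c(50, 50)), 1))
  db$choline[3] <- NA
  out <- resolve_recipes(db, nested)
  expect_equal(out$choline[3], (225 + 16.2) / 2)
  expect_equal(out$choline[4], out$choline[3])
  expect_equal(out$source[3], "recipe")
  cyc <- list(
    recipe_spec("20205099",
                tibble::tibble(food_id = "20205007", raw_weight = 1), 1),
    recipe_spec("20205007",
                tibble::tibble(food_id = "20205099", raw_weight = 1), 1))
  expect_error(resolve_recipes(db, cyc), "20205",
               class = "cholinedb_cycle_error")
  orphan <- list(recipe_spec("20205007",
                             tibble::tibble(food_id = "99999999",
                                            raw_weight = 1), 1))
  expect_error(resolve_recipes(db, orphan), "99999999",
               class = "cholinedb_compilation_error")
})

test_that("the unmatched-zero policy flags zeros without touching values", {
  fd <- generate_food_db(10, 0.7, 0, seed = 5)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  expect_equal(nrow(db), 10)
  expect_equal(sum(db$unmatched_zero), 3)
  expect_true(all(db$choline[db$unmatched_zero] == 0))
  expect_true(all(db$source[db$unmatched_zero] == "unmatched_zero"))
  # zeroing a food that already carries a value is refused
  expect_error(apply_zero_policy(db, db$food_id[!db$unmatched_zero][1]),
               class = "cholinedb_policy_error")
  # no unmatched foods: database unchanged
  expect_identical(apply_zero_policy(db, character(0)), db)
})

test_that("QA checks rank, range-check and sample reproducibly", {
  fd <- generate_food_db(100, 1, 0, seed = 9)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  qa1 <- qa_checks(db, fraction = 0.10, seed = 42)
  qa2 <- qa_checks(db, fraction = 0.10, seed = 42)
  expect_length(qa1$verification_sample, 10)
  expect_identical(qa1$verification_sample, qa2$verification_sample)
  expect_false(identical(qa1$verification_sample,
                         qa_checks(db, seed = 43)$verification_sample))
  # ranking is descending in value
  vals <- db$choline[match(qa1$ranked, db$food_id)]
  expect_true(all(diff(vals) <= 0))
  # an implausible value trips its group bound
  db$choline[1] <- 10000
  bounds <- tibble::tibble(group2 = db$group2[1], lower = 0, upper = 2000)
  qa3 <- qa_checks(db, bounds = bounds, seed = 1)
  expect_equal(qa3$violations$food_id, db$food_id[1])
  expect_equal(nrow(qa_checks(db, seed = 1)$violations), 0)
  expect_error(qa_checks(db, fraction = 0), class = "cholinedb_parameter_error")
})

test_that("duplicate-calculation QA flags a corrupted recipe value", {
  fd <- generate_food_db(80, 1, 5, seed = 13)
  db <- compile_database(fd$food, fd$donors, fd$matches, fd$recipes)
  clean <- qa_checks(db, seed = 1, recipes = fd$recipes)
  expect_length(clean$duplicate_mismatches, 0)
  rid <- names(fd$recipes)[1]
  db$choline[db$food_id == rid] <- db$choline[db$food_id == rid] + 5
  dirty <- qa_checks(db, seed = 1, recipes = fd$recipes)
  expect_equal(dirty$duplicate_mismatches, rid)
})

test_that("coverage statistics count genuine values only", {
  fd <- generate_food_db(10, 0.9, 0, seed = 2)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  cov <- coverage_stats(db)
  expect_equal(cov$n_with_value, 9)
  expect_equal(cov$percent_of_total, 90.00)
  fd_full <- generate_food_db(10, 1, 0, seed = 2)
  full <- compile_database(fd_full$food, fd_full$donors, fd_full$matches)
  expect_equal(coverage_stats(full)$percent_of_total, 100.00)
})
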