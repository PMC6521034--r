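test_that("weighted means follow the weights", {
  expect_equal(weighted_mean(c(100, 200), c(1, 1)), 150)
  expect_equal(weighted_mean(c(100, 200), c(3, 1)), 125)
  expect_equal(weighted_mean(151.5, 2.7), 151.5)
  expect_error(weighted_mean(c(1, 2), c(-1, 1)),
               class = "cholinedb_validation_error")
})

test_that("grouped jackknife combines replicate deviations", {
  # constant statistic: no variation, SE 0
  expect_equal(jackknife_se(function(v, w) 42, 1:5, rep(1, 5),
                            matrix(1, 5, 4)), 0)
  # two replicates at theta_full +/- 1 give SE exactly 1
  vals <- c(0, 2)
  rw <- cbind(c(0, 1), c(1, 0))
  expect_equal(jackknife_se(weighted_mean, vals, c(1, 1), rw), 1)
  expect_warning(jackknife_se(weighted_mean, vals, c(1, 1),
                              cbind(c(0, 0), c(1, 1), c(1, 0))),
                 "all zero")
})

test_that("jackknife SE matches brute-force delete-one on small samples", {
  set.seed(8)
  for (n in c(5, 9, 12)) {
    x <- rnorm(n, 250, 30)
    rw <- loo_replicates(n)
    se <- jackknife_se(weighted_mean, x, rep(1, n), rw)
    # independent oracle: enumerate every leave-one-out subset directly
    loo_means <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
    se_brute <- sqrt((n - 1) / n * sum((loo_means - mean(x))^2))
    expect_equal(se, se_brute, tolerance = 1e-10)
  }
})

test_that("the 95% CI construction reproduces reported survey rows", {
  ci <- confidence_interval(185.36, 3.43)
  expect_equal(round(unname(ci), 2), c(178.50, 192.22))
  ci2 <- confidence_interval(275.37, 6.24)
  expect_equal(round(unname(ci2), 2), c(262.89, 287.85))
  expect_equal(unname(confidence_interval(100, 0)), c(100, 100))
  expect_equal(unname(confidence_interval(100, 10, multiplier = 1.96)),
               c(80.4, 119.6))
})

test_that("weighted quartile bounds walk the cumulative weight", {
  expect_equal(unname(weighted_quartiles(1:8, rep(1, 8))), c(1, 2, 4, 6, 8))
  expect_equal(unname(weighted_quartiles(rep(7, 5), runif(5))), rep(7, 5))
  x <- c(3, 9, 1, 5, 5, 2)
  w <- c(2, 1, 3, 1, 1, 2)
  expect_equal(weighted_quartiles(x, w), weighted_quartiles(x, 2 * w))
  # containment: each quartile interval holds ~25% of the total weight
  set.seed(15)
  x <- rnorm(200)
  w <- runif(200, 0.5, 2)
  q <- weighted_quartiles(x, w)
  cum <- sapply(q[2:4], function(b) sum(w[x <= b]) / sum(w))
  expect_true(all(cum >= c(0.25, 0.5, 0.75)))
  expect_true(all(cum - c(0.25, 0.5, 0.75) <= max(w) / sum(w)))
})

test_that("AI attainment counts respondents at or above their AI", {
  ai <- default_ai_reference()
  n <- 464
  resp <- tibble::tibble(resp_id = sprintf("R%05d", 1:n), age = 2,
                         sex = "female", life_stage = "none", weight = 1)
  usual <- c(rep(210, 311), rep(150, n - 311))  # AI is 200 at ages 2-3
  att <- ai_attainment(usual, resp, ai)
  expect_equal(att$pct_at_or_above, 67.03)
  expect_equal(att$n_at_or_above, 311)
  expect_equal(att$ai, 200)
  # boundaries
  expect_equal(ai_attainment(rep(100, 10), resp[1:10, ], ai)$pct_at_or_above, 0)
  expect_equal(ai_attainment(rep(100, 10), resp[1:10, ], ai)$pop_equivalent_at_or_above, 0)
  expect_equal(ai_attainment(rep(200, 10), resp[1:10, ], ai)$pct_at_or_above, 100)
})

test_that("group summaries partition respondents and mirror the survey table", {
  fd <- generate_food_db(100, 1, 0, seed = 10)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  sv <- generate_survey(db, 600, seed = 10)
  daily <- daily_intake(sv$events, db, sv$design)
  comp <- fit_variance_components(daily, sv$respondents)
  u <- usual_intake(daily, comp, sv$respondents)
  gs <- suppressMessages(
    build_group_summaries(u, sv$respondents, default_ai_reference()))
  total <- gs[gs$group_label == "Total", ]
  # exclusive sex x age and life-stage rows partition the total
  exclusive <- setdiff(gs$group_label, c("Total", "Childbearing 16-44 years"))
  expect_equal(sum(gs$n[gs$group_label %in% exclusive]), total$n)
  expect_equal(sum(gs$pop_equivalent[gs$group_label %in% exclusive]),
               total$pop_equivalent, tolerance = 1e-9)
  # basic row coherence
  expect_true(all(gs$ci_low <= gs$mean & gs$mean <= gs$ci_high))
  expect_true(all(gs$q_min <= gs$q1 & gs$q1 <= gs$median &
                    gs$median <= gs$q3 & gs$q3 <= gs$q_max))
  expect_true(all(gs$pct_at_or_above_ai >= 0 & gs$pct_at_or_above_ai <= 100,
                  na.rm = TRUE))
  # weight-scale invariance: scaling weights scales only the population
  # equivalents
  sv2 <- sv
  wcols <- c("weight", grep("^repw_", names(sv$respondents), value = TRUE))
  sv2$respondents[wcols] <- sv$respondents[wcols] * 3
  gs2 <- suppressMessages(
    build_group_summaries(u, sv2$respondents, default_ai_reference()))
  expect_equal(gs2$pop_equivalent, 3 * gs$pop_equivalent)
  expect_equal(gs2$mean, gs$mean)
  expect_equal(gs2$se, gs$se)
  expect_equal(gs2$pct_at_or_above_ai, gs$pct_at_or_above_ai)
})

test_that("a two-person group reproduces the small-sample mean and SE", {
  ai <- default_ai_reference()
  resp <- tibble::tibble(resp_id = c("P1", "P2"), age = 17, sex = "female",
                         life_stage = "pregnant", weight = c(1, 1))
  u <- tibble::tibble(resp_id = c("P1", "P2"), usual = c(124.56, 178.44))
  gs <- suppressMessages(build_group_summaries(
    u, resp, ai,
    grouping = tibble::tibble(group_label = "Pregnant 14-18 years",
                              sex = "female", age_min = 14, age_max = 18,
                              life_stage = "pregnant")))
  expect_equal(gs$mean, 151.50)
  expect_equal(gs$se, 26.94)  # sd/sqrt(n) fallback without replicate weights
  expect_equal(gs$pct_at_or_above_ai, 0)
})

test_that("empty groups are omitted with a notice", {
  ai <- default_ai_reference()
  resp <- simple_respondents(5)
  u <- tibble::tibble(resp_id = resp$resp_id, usual = rep(250, 5))
  expect_message(
    gs <- build_group_summaries(u, resp, ai),
    "empty")
  expect_false("Pregnant 19-50 years" %in% gs$group_label)
})
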