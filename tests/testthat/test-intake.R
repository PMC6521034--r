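test_that("person-day intakes sum events through the database", {
  db <- tiny_db()  # egg 225 mg/100 g, milk 16.2, stew 60
  events <- tibble::tibble(resp_id = c("A", "A", "B"),
                           day = c(1L, 1L, 1L),
                           food_id = c("28101001", "13102031", "28101001"),
                           grams = c(90, 100, 40))
  daily <- daily_intake(events, db)
  expect_equal(daily$intake[daily$resp_id == "A"], 90 * 225 / 100 + 16.2)
  expect_equal(daily$intake[daily$resp_id == "B"], 90)
  # a designed person-day with no events is a true zero
  design <- tibble::tibble(resp_id = c("A", "A", "B"),
                           day = c(1L, 2L, 1L))
  daily2 <- daily_intake(events, db, design)
  expect_equal(daily2$intake[daily2$resp_id == "A" & daily2$day == 2], 0)
  expect_error(daily_intake(dplyr::mutate(events, food_id = "00000000"), db),
               "00000000", class = "cholinedb_compilation_error")
})

test_that("one event of 90 g at 225 mg/100 g gives 202.5 mg", {
  db <- tiny_db()
  ev <- tibble::tibble(resp_id = "A", day = 1L, food_id = "28101001",
                       grams = 90)
  expect_equal(daily_intake(ev, db)$intake, 202.5)
})

test_that("variance decomposition handles degenerate and balanced cases", {
  # equal person means: all spread is within-person
  daily <- tibble::tibble(resp_id = rep(sprintf("R%05d", 1:40), each = 2),
                          day = rep(1:2, 40),
                          intake = rep(c(90, 110), 40))
  resp <- simple_respondents(40)
  comp <- fit_variance_components(daily, resp, formula = intake ~ 1)
  expect_equal(comp$sigma2_between, 0)
  expect_equal(comp$sigma2_within, 200)  # (10^2 + 10^2)/2 per person
  # lambda with equal components and 2 days is 2/3
  comp$sigma2_between <- comp$sigma2_within
  lam <- comp$sigma2_between / (comp$sigma2_between + comp$sigma2_within / 2)
  expect_equal(lam, 2 / 3)
  # all persons single-day: within-variance unidentifiable
  one_day <- daily[daily$day == 1, ]
  expect_error(fit_variance_components(one_day, resp, formula = intake ~ 1),
               class = "cholinedb_estimation_error")
})

test_that("moment estimates agree with a one-way ANOVA oracle on balanced data", {
  set.seed(21)
  k <- 60
  daily <- tibble::tibble(resp_id = rep(sprintf("R%05d", 1:k), each = 2),
                          day = rep(1:2, k),
                          intake = rep(rnorm(k, 250, 20), each = 2) +
                            rnorm(2 * k, 0, 40))
  resp <- simple_respondents(k)
  comp <- fit_variance_components(daily, resp, formula = intake ~ 1)
  # independent route: classic balanced one-way ANOVA mean squares
  fit <- stats::aov(intake ~ factor(resp_id), data = daily)
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_equal(comp$sigma2_within, ms[2], tolerance = 1e-10)
  expect_equal(comp$sigma2_between, max(0, (ms[1] - ms[2]) / 2),
               tolerance = 1e-10)
})

test_that("usual intakes shrink person means toward the prediction", {
  # lambda = 1 when within-variance is 0: usual equals the person mean
  daily <- tibble::tibble(resp_id = rep(sprintf("R%05d", 1:30), each = 2),
                          day = rep(1:2, 30),
                          intake = rep(seq(200, 300, length.out = 30), each = 2))
  resp <- simple_respondents(30)
  comp <- fit_variance_components(daily, resp, formula = intake ~ 1)
  expect_equal(comp$sigma2_within, 0)
  u <- usual_intake(daily, comp, resp)
  expect_equal(u$usual, u$person_mean)
  # hand case: mean 300, prediction 250, lambda 2/3 -> 283.33
  expect_equal(250 + 2 / 3 * (300 - 250), 283.3333, tolerance = 1e-4)
})

test_that("shrinkage bounds and variance ordering hold on synthetic surveys", {
  fd <- generate_food_db(100, 1, 0, seed = 4)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  sv <- generate_survey(db, 300, 400, 1600, seed = 4)
  daily <- daily_intake(sv$events, db, sv$design)
  comp <- fit_variance_components(daily, sv$respondents)
  u <- usual_intake(daily, comp, sv$respondents)
  # every usual intake lies between the prediction and the person mean
  lo <- pmin(u$prediction, u$person_mean)
  hi <- pmax(u$prediction, u$person_mean)
  expect_true(all(u$usual >= lo - 1e-9 & u$usual <= hi + 1e-9))
  # usual intakes are less dispersed than person means
  expect_lt(stats::var(u$usual), stats::var(u$person_mean))
  # zero shrinkage limit: lambda = 0 returns the prediction
  comp0 <- comp
  comp0$lambda <- function(d) 0
  u0 <- usual_intake(daily, comp0, sv$respondents)
  expect_equal(u0$usual, u0$prediction)
})

test_that("variance components cross-check against a mixed-model fit", {
  skip_if_not_installed("lme4")
  fd <- generate_food_db(100, 1, 0, seed = 6)
  db <- compile_database(fd$food, fd$donors, fd$matches)
  sv <- generate_survey(db, 500, 400, 1600, day2_fraction = 1, seed = 6)
  daily <- daily_intake(sv$events, db, sv$design)
  comp <- fit_variance_components(daily, sv$respondents,
                                  formula = intake ~ 1)
  lf <- lme4::lmer(intake ~ 1 + (1 | resp_id), data = daily, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(comp$sigma2_between, vc$vcov[1], tolerance = 0.05)
  expect_equal(comp$sigma2_within, vc$vcov[2], tolerance = 0.05)
})
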