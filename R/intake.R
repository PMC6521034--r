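# From reported intake events to per-person usual (habitual) intake:
# person-day totals, a covariate regression, a one-way method-of-moments
# decomposition of its residuals, and shrinkage of person means toward the
# covariate prediction.

#' Survey age bands
#'
#' Assigns each age (whole years) to the survey's reporting bands:
#' 2-3, 4-8, 9-13, 14-18, 19-64 and 65-85 years.
#'
#' @param age Integer ages in years.
#' @return Ordered factor of band labels; ages outside 2-85 give `NA`.
#' @export
age_band <- function(age) {
  breaks <- c(2, 4, 9, 14, 19, 65, 86)
  labels <- c("2-3", "4-8", "9-13", "14-18", "19-64", "65-85")
  cut(age, breaks = breaks, labels = labels, right = FALSE)
}

#' Per-person-day nutrient intake
#'
#' Sums `grams x value/100` over each person-day's reported foods. Person-days
#' present in the survey design but with no reported events are retained with
#' an intake of 0 (the nutrient is consumed daily; zero days are real zeros).
#'
#' @param events Tibble of intake events: `resp_id`, `day` (1 or 2),
#'   `food_id`, `grams`.
#' @param db Compiled nutrient database; every `food_id` in `events` must
#'   resolve.
#' @param design Optional tibble of `resp_id`, `day` enumerating the
#'   person-days in the survey; defaults to the person-days present in
#'   `events`.
#' @param nutrient Database column to use (default `"choline"`).
#' @return Tibble `resp_id`, `day`, `intake` (mg/day).
#' @export
daily_intake <- function(events, db, design = NULL, nutrient = "choline") {
  idx <- match(events$food_id, db$food_id)
  if (any(is.na(idx))) {
    abort(sprintf("unresolvable food id(s): %s",
                  paste(unique(events$food_id[is.na(idx)]), collapse = ", ")),
          class = "cholinedb_compilation_error")
  }
  mg <- events$grams * db[[nutrient]][idx] / 100
  totals <- tibble::tibble(resp_id = events$resp_id, day = events$day,
                           mg = mg) %>%
    dplyr::group_by(.data$resp_id, .data$day) %>%
    dplyr::summarise(intake = sum(.data$mg), .groups = "drop")
  if (is.null(design)) {
    design <- dplyr::distinct(events[, c("resp_id", "day")])
  }
  design %>%
    dplyr::left_join(totals, by = c("resp_id", "day")) %>%
    dplyr::mutate(intake = dplyr::coalesce(.data$intake, 0)) %>%
    dplyr::arrange(.data$resp_id, .data$day)
}

#' Fit variance components for usual-intake estimation
#'
#' Models person-day intakes as `covariate prediction + person effect +
#' day-to-day noise`. A least-squares regression on the covariates is fitted
#' to all person-days; its residuals are decomposed by the one-way
#' method-of-moments into between-person and within-person variance, using
#' the unbalanced-design ANOVA estimator (within from the pooled
#' within-person sum of squares; between from the between-person mean square
#' with the average-group-size correction). Negative moment estimates are
#' truncated at zero.
#'
#' @param daily Person-day intakes ([daily_intake()]).
#' @param respondents Respondent tibble with `resp_id` and the covariates.
#' @param formula Regression formula for the covariate model; the response
#'   must be `intake`. The default crosses age band with sex (the survey's
#'   reporting strata), so stratum-level mean structure is not absorbed
#'   into the between-person variance.
#' @param transform `"none"` (default) or `"log"`; under `"log"` the model is
#'   fitted on `log(intake + 1)` and usual intakes are back-transformed by
#'   the naive exponential (an extension; the default analysis is on the
#'   original scale).
#' @return Object of class `choline_varcomp`: variance components, the fitted
#'   covariate model, and `lambda(d)`, the shrinkage factor
#'   `sigma2_between / (sigma2_between + sigma2_within / d)` for `d` recall
#'   days.
#' @export
fit_variance_components <- function(daily, respondents,
                                    formula = intake ~ age_band(age) * sex,
                                    transform = c("none", "log")) {
  transform <- match.arg(transform)
  df <- dplyr::inner_join(daily, respondents, by = "resp_id")
  if (nrow(df) < nrow(daily)) {
    abort("person-days with no matching respondent record",
          class = "cholinedb_validation_error")
  }
  if (transform == "log") df$intake <- log(df$intake + 1)
  d_i <- table(df$resp_id)
  if (all(d_i < 2)) {
    abort("within-person variance unidentifiable: no respondent has 2 days",
          class = "cholinedb_estimation_error")
  }
  fit <- stats::lm(formula, data = df)
  r <- stats::residuals(fit)
  person <- factor(df$resp_id)
  k <- nlevels(person)
  N <- length(r)
  r_bar_i <- tapply(r, person, mean)
  d_vec <- as.numeric(table(person))
  ssw <- sum((r - r_bar_i[person])^2)
  sigma2_within <- ssw / (N - k)
  r_bar <- mean(r)
  ssb <- sum(d_vec * (as.numeric(r_bar_i) - r_bar)^2)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(d_vec^2) / N) / (k - 1)
  sigma2_between <- max(0, (msb - sigma2_within) / n0)
  lambda <- function(d) {
    denom <- sigma2_between + sigma2_within / d
    ifelse(denom <= 0, 1, sigma2_between / denom)
  }
  structure(list(sigma2_between = sigma2_between,
                 sigma2_within = sigma2_within,
                 lambda = lambda,
                 model = fit,
                 formula = formula,
                 transform = transform),
            class = "choline_varcomp")
}

#' @export
print.choline_varcomp <- function(x, ...) {
  cat("Usual-intake variance components\n")
  cat(sprintf("  between-person: %.2f (mg/day)^2\n", x$sigma2_between))
  cat(sprintf("  within-person:  %.2f (mg/day)^2\n", x$sigma2_within))
  cat(sprintf("  shrinkage lambda(2 days): %.4f\n", x$lambda(2)))
  invisible(x)
}

#' Estimate per-person usual intakes by residual shrinkage
#'
#' Each person's usual intake is the covariate prediction plus the person's
#' observed deviation from it shrunken by `lambda(d)`, where `d` is that
#' person's number of recall days:
#' `usual_i = prediction_i + lambda(d_i) * (person mean_i - prediction_i)`.
#' Persons with a single day are shrunken with `lambda(1)`; no second day is
#' imputed.
#'
#' @param daily Person-day intakes ([daily_intake()]).
#' @param components Fitted [fit_variance_components()] object.
#' @param respondents Respondent tibble (covariates for the prediction).
#' @return Tibble `resp_id`, `n_days`, `person_mean`, `prediction`, `usual`
#'   (all intakes in mg/day, on the original scale).
#' @export
usual_intake <- function(daily, components, respondents) {
  per <- daily %>%
    dplyr::group_by(.data$resp_id) %>%
    dplyr::summarise(n_days = dplyr::n(),
                     person_mean = mean(.data$intake), .groups = "drop") %>%
    dplyr::inner_join(respondents, by = "resp_id")
  if (components$transform == "log") {
    obs <- log(per$person_mean + 1)
  } else {
    obs <- per$person_mean
  }
  pred <- stats::predict(components$model, newdata = per)
  lam <- components$lambda(per$n_days)
  usual <- pred + lam * (obs - pred)
  if (components$transform == "log") {
    usual <- pmax(exp(usual) - 1, 0)
    pred <- pmax(exp(pred) - 1, 0)
  }
  tibble::tibble(resp_id = per$resp_id, n_days = per$n_days,
                 person_mean = per$person_mean, prediction = as.numeric(pred),
                 usual = as.numeric(usual))
}
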