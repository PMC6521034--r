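# Per-food-group survey-weighted regression of total daily nutrient intake
# on food-group consumption (per 100 g) plus covariates, with
# grouped-jackknife SEs and percent variance explained.

#' Fit one food-group regression model
#'
#' Weighted least squares of total daily intake (mg/day) on the food group's
#' consumption rescaled to 100 g units, plus the survey covariates. Standard
#' errors come from the grouped jackknife: the model is refitted under every
#' replicate-weight column and squared coefficient deviations are combined
#' as in [jackknife_se()]. p-values use a t reference with
#' `max(R - parameters, 1)` degrees of freedom.
#'
#' @param data Data frame with the response, the group grams column and the
#'   covariates.
#' @param weights Full-sample weights.
#' @param replicate_weights Matrix of replicate-weight columns (R >= 2).
#' @param group_col Name of the food-group grams/day column; it enters the
#'   model divided by 100, so its coefficient reads "mg choline per 100 g of
#'   the food group".
#' @param covariates Covariate column names entering linearly (activity and
#'   education as integer levels 1-5, sex as a factor or indicator).
#' @param response Name of the dependent-variable column (default
#'   `"total"`, mg/day).
#' @param group_label Label carried into the result (defaults to
#'   `group_col`).
#' @return Object of class `choline_group_model`: `coefficients` tibble
#'   (`term`, `estimate`, `jackknife_se`, `t`, `p`, `significant` at
#'   p < 0.05), `r2_pct` (weighted, 0-100), `group_label`, `n`, `R`.
#' @export
fit_group_model <- function(data, weights, replicate_weights,
                            group_col = "group_grams",
                            covariates = c("energy", "activity_level",
                                           "sex", "age", "education_level"),
                            response = "total",
                            group_label = group_col) {
  data <- as.data.frame(data)
  data$.per100 <- data[[group_col]] / 100
  fml <- stats::as.formula(paste(
    response, "~ .per100 +", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(fml, data)
  y <- data[[response]]
  if (nrow(X) < ncol(X) + 2) {
    abort("too few observations for the model dimension",
          class = "cholinedb_estimation_error")
  }
  fit <- stats::lm.wfit(X, y, weights)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1):ncol(X)]]
    aliased <- sub("^\\.per100$", group_col, aliased)
    abort(sprintf("collinear design; aliased column(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "cholinedb_collinearity_error")
  }
  coef_full <- fit$coefficients
  rw <- as.matrix(replicate_weights)
  R <- ncol(rw)
  if (R < 2) {
    abort("need at least 2 replicate-weight columns",
          class = "cholinedb_validation_error")
  }
  coef_rep <- apply(rw, 2, function(w) stats::lm.wfit(X, y, w)$coefficients)
  dev2 <- (coef_rep - coef_full)^2
  se <- sqrt((R - 1) / R * rowSums(dev2))
  tval <- coef_full / se
  dfree <- max(R - length(coef_full), 1)
  pval <- 2 * stats::pt(-abs(tval), df = dfree)
  ybar <- sum(weights * y) / sum(weights)
  ss_tot <- sum(weights * (y - ybar)^2)
  ss_res <- sum(weights * fit$residuals^2)
  r2_pct <- 100 * (1 - ss_res / ss_tot)
  terms <- names(coef_full)
  terms[terms == ".per100"] <- group_col
  structure(list(
    coefficients = tibble::tibble(term = terms,
                                  estimate = unname(coef_full),
                                  jackknife_se = unname(se),
                                  t = unname(tval), p = unname(pval),
                                  significant = unname(pval) < 0.05),
    r2_pct = r2_pct, group_label = group_label,
    n = nrow(X), R = R, df = dfree),
    class = "choline_group_model")
}

#' @export
print.choline_group_model <- function(x, ...) {
  cat(sprintf("Food-group model: %s (n = %d, R = %d replicates)\n",
              x$group_label, x$n, x$R))
  cat(sprintf("  variance explained: %.2f%%\n", x$r2_pct))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Rank fitted food-group models by variance explained
#'
#' @param results List of `choline_group_model` objects.
#' @param exclude Group labels to drop (e.g. infant formula and infant
#'   foods groups, which fall outside the surveyed age range).
#' @return Tibble `group_label`, `r2_pct`, `coefficient`, `p`, ordered by
#'   descending `r2_pct`; ties break by ascending group label.
#' @export
rank_models <- function(results, exclude = character()) {
  rows <- purrr::map_dfr(results, function(m) {
    lead <- m$coefficients[2, ]  # the food-group term follows the intercept
    tibble::tibble(group_label = m$group_label, r2_pct = m$r2_pct,
                   coefficient = lead$estimate, p = lead$p)
  })
  rows <- rows[!(rows$group_label %in% exclude), ]
  rows[order(-rows$r2_pct, rows$group_label), ]
}

#' Per-person mean grams/day of one food group
#'
#' Averages a respondent's reported grams of the food group over their
#' surveyed days (days with no consumption of the group count as 0 g).
#'
#' @param events Intake events.
#' @param db Compiled database (for the group codes).
#' @param respondents Respondent tibble.
#' @param group_code Group prefix code (at the level implied by its width).
#' @param design Person-day design tibble (`resp_id`, `day`); defaults to
#'   the person-days present in `events`.
#' @return Tibble `resp_id`, `group_grams` (g/day).
#' @export
group_grams_per_day <- function(events, db, respondents, group_code,
                                design = NULL) {
  level <- nchar(group_code)
  stopifnot(level %in% c(2, 3, 5))
  idx <- match(events$food_id, db$food_id)
  in_grp <- db[[paste0("group", level)]][idx] == group_code
  if (is.null(design)) {
    design <- dplyr::distinct(events[, c("resp_id", "day")])
  }
  n_days <- dplyr::count(design, .data$resp_id, name = "n_days")
  ev <- events[in_grp, ] %>%
    dplyr::group_by(.data$resp_id) %>%
    dplyr::summarise(tot_grams = sum(.data$grams), .groups = "drop")
  tibble::tibble(resp_id = respondents$resp_id) %>%
    dplyr::left_join(ev, by = "resp_id") %>%
    dplyr::left_join(n_days, by = "resp_id") %>%
    dplyr::mutate(group_grams = dplyr::coalesce(.data$tot_grams, 0) /
                    dplyr::coalesce(.data$n_days, 1L)) %>%
    dplyr::select("resp_id", "group_grams")
}

#' Fit food-group models for every group in the database
#'
#' Builds the per-group model data (usual intake as the response by default,
#' per-person mean grams of the group, survey covariates) and fits
#' [fit_group_model()] for each 3-digit group with any consumption.
#'
#' @param events Intake events.
#' @param db Compiled database.
#' @param respondents Respondent tibble (with `weight`, replicate-weight
#'   columns, `energy`, `activity_level`, `education_level`, `age`, `sex`).
#' @param usual Usual-intake tibble ([usual_intake()]).
#' @param level Grouping level (default 3).
#' @param exclude Group codes to skip (e.g. infant food groups).
#' @param rep_prefix Replicate-weight column prefix.
#' @param min_consumers Skip groups eaten by fewer respondents than this.
#' @return Named list of `choline_group_model` objects.
#' @export
fit_group_models <- function(events, db, respondents, usual, level = 3,
                             exclude = character(), rep_prefix = "repw_",
                             min_consumers = 10) {
  grp_col <- paste0("group", level)
  idx <- match(events$food_id, db$food_id)
  codes <- sort(setdiff(unique(db[[grp_col]][idx]), exclude))
  rep_cols <- grep(paste0("^", rep_prefix), names(respondents), value = TRUE)
  base <- dplyr::inner_join(respondents,
                            usual[, c("resp_id", "usual")], by = "resp_id")
  out <- list()
  for (code in codes) {
    gg <- group_grams_per_day(events, db, base, code)
    dat <- dplyr::inner_join(base, gg, by = "resp_id")
    if (sum(dat$group_grams > 0) < min_consumers) next
    dat$total <- dat$usual
    m <- tryCatch(
      fit_group_model(dat, weights = dat$weight,
                      replicate_weights = as.matrix(dat[, rep_cols]),
                      group_col = "group_grams", group_label = code),
      cholinedb_collinearity_error = function(e) NULL)
    if (!is.null(m)) out[[code]] <- m
  }
  out
}
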