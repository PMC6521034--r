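# Design-based descriptive statistics: weighted means, delete-a-group
# jackknife standard errors from replicate weights, weighted quartile
# bounds, population equivalents and AI attainment by demographic group.

#' Weighted mean
#'
#' @param values Numeric vector (mg/day).
#' @param weights Positive weights of the same length.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  # replicate-weight columns legitimately contain zeros (deleted groups)
  if (any(weights < 0) || sum(weights) == 0) {
    abort("weights must be >= 0 with a positive total",
          class = "cholinedb_validation_error")
  }
  sum(weights * values) / sum(weights)
}

#' Grouped (delete-a-group) jackknife standard error
#'
#' Recomputes a statistic under each replicate-weight column and combines
#' the squared deviations from the full-sample estimate:
#' `SE = sqrt(((R - 1) / R) * sum_g (theta_g - theta_full)^2)`.
#'
#' @param statistic Function of `(values, weights)` returning a scalar.
#' @param values Numeric vector.
#' @param weights Full-sample weights.
#' @param replicate_weights Matrix with one column per replicate (R >= 2
#'   columns, rows aligned with `values`).
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(statistic, values, weights, replicate_weights) {
  replicate_weights <- as.matrix(replicate_weights)
  R <- ncol(replicate_weights)
  if (R < 2) {
    abort("need at least 2 replicate-weight columns",
          class = "cholinedb_validation_error")
  }
  all_zero <- colSums(abs(replicate_weights)) == 0
  if (any(all_zero)) {
    warn(sprintf("replicate-weight column(s) all zero: %s",
                 paste(which(all_zero), collapse = ", ")))
  }
  theta_full <- statistic(values, weights)
  theta_g <- apply(replicate_weights, 2, function(w) {
    tryCatch(statistic(values, w), error = function(e) NA_real_)
  })
  # a replicate under which the statistic is undefined (e.g. a small domain
  # whose members were all deleted) contributes zero deviation
  theta_g[!is.finite(theta_g)] <- theta_full
  sqrt((R - 1) / R * sum((theta_g - theta_full)^2))
}

#' 95% confidence interval from a mean and standard error
#'
#' Constructed as `mean +/- multiplier * SE`; the default multiplier of 2 is
#' the package's reporting convention (a 1.96 option is available).
#'
#' @param mean,se Point estimate and standard error.
#' @param multiplier CI half-width in SE units (default 2).
#' @return Named numeric `c(low, high)`.
#' @export
confidence_interval <- function(mean, se, multiplier = 2) {
  c(low = mean - multiplier * se, high = mean + multiplier * se)
}

#' Weighted quartile bounds
#'
#' Returns the five bounds (minimum, Q1, median, Q3, maximum) delimiting the
#' four contiguous weighted quartile intervals: each interior bound is the
#' lowest value whose cumulative normalised weight reaches the target
#' fraction. Ties are kept in value order (stable).
#'
#' @param values Numeric vector.
#' @param weights Positive weights.
#' @return Numeric vector of 5 non-decreasing bounds.
#' @export
weighted_quartiles <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  bound <- function(f) v[which(cw >= f - 1e-12)[1]]
  out <- c(v[1], bound(0.25), bound(0.5), bound(0.75), v[length(v)])
  names(out) <- c("min", "q1", "median", "q3", "max")
  out
}

#' AI attainment within a respondent group
#'
#' Counts persons whose usual intake meets or exceeds their Adequate
#' Intake. The percentage is computed on unweighted counts (matching the
#' survey reporting convention); the population equivalent of attainers is
#' the weighted companion figure. Members with no applicable AI are excluded
#' from the denominator with a notice.
#'
#' @param usual Usual intakes (mg/day), aligned with `respondents`.
#' @param respondents Respondent tibble with `age`, `sex`, `life_stage`,
#'   `weight`.
#' @param ai_table AI reference ([read_ai_reference()]).
#' @return List: `n` (with an AI), `n_at_or_above`, `pct_at_or_above`
#'   (rounded to 2 decimals), `pop_equivalent_at_or_above`, `ai` (the
#'   group's AI when unique, else `NA`), `n_excluded`.
#' @export
ai_attainment <- function(usual, respondents, ai_table) {
  ai <- purrr::pmap_dbl(
    list(respondents$age, respondents$sex, respondents$life_stage),
    lookup_ai, ai_table = ai_table)
  excl <- is.na(ai)
  if (any(excl)) {
    inform(sprintf("%d respondent(s) without an applicable AI excluded",
                   sum(excl)))
  }
  usual <- usual[!excl]
  w <- respondents$weight[!excl]
  ai <- ai[!excl]
  at <- usual >= ai
  n <- length(usual)
  list(n = n,
       n_at_or_above = sum(at),
       pct_at_or_above = if (n > 0) round(100 * sum(at) / n, 2) else NA_real_,
       pop_equivalent_at_or_above = sum(w[at]),
       ai = if (length(unique(ai)) == 1) ai[1] else NA_real_,
       n_excluded = sum(excl))
}

#' Default demographic grouping
#'
#' The survey's reporting rows: total; children 2-3 and 4-8 (both sexes);
#' male and female bands 9-13, 14-18, 19-64, 65-85; pregnant 14-18 and
#' 19-50; lactating 19-50; and females of childbearing age 16-44 excluding
#' pregnant and breastfeeding women. Pregnancy/lactation rows take
#' precedence over the plain female bands.
#'
#' @return Tibble defining one group per row: `group_label`, `sex`,
#'   `age_min`, `age_max`, `life_stage` (`"any"`, `"none"`, `"pregnant"`,
#'   `"lactating"`).
#' @export
default_grouping <- function() {
  tibble::tribble(
    ~group_label,                  ~sex,     ~age_min, ~age_max, ~life_stage,
    "Total",                       "any",    2,        85,       "any",
    "2-3 years",                   "any",    2,        3,        "none",
    "4-8 years",                   "any",    4,        8,        "none",
    "Male 9-13 years",             "male",   9,        13,       "none",
    "Male 14-18 years",            "male",   14,       18,       "none",
    "Male 19-64 years",            "male",   19,       64,       "none",
    "Male 65-85 years",            "male",   65,       85,       "none",
    "Female 9-13 years",           "female", 9,        13,       "none",
    "Female 14-18 years",          "female", 14,       18,       "none",
    "Pregnant 14-18 years",        "female", 14,       18,       "pregnant",
    "Female 19-64 years",          "female", 19,       64,       "none",
    "Pregnant 19-50 years",        "female", 19,       50,       "pregnant",
    "Lactating 19-50 years",       "female", 19,       50,       "lactating",
    "Female 65-85 years",          "female", 65,       85,       "none",
    "Childbearing 16-44 years",    "female", 16,       44,       "none")
}

# Logical membership of each respondent in one grouping row. life_stage
# semantics: "any" = everyone; "none" = persons with no pregnancy/lactation
# (so pregnancy rows take precedence over plain bands); otherwise exact.
.group_members <- function(respondents, g) {
  sex_ok <- g$sex == "any" | respondents$sex == g$sex
  age_ok <- respondents$age >= g$age_min & respondents$age <= g$age_max
  ls_ok <- switch(g$life_stage,
                  any = rep(TRUE, nrow(respondents)),
                  none = respondents$life_stage == "none",
                  respondents$life_stage == g$life_stage)
  sex_ok & age_ok & ls_ok
}

#' Build Table-1-style group summaries
#'
#' One row per configured demographic group with unweighted n, population
#' equivalent (sum of weights), weighted mean, grouped-jackknife SE, 95% CI
#' (mean +/- 2 SE), weighted quartile bounds, and AI attainment. Empty
#' groups are omitted with a notice. Means, SEs, CI bounds and quartile
#' bounds are rounded to 2 decimals; population equivalents are left
#' unrounded.
#'
#' @param usual Usual-intake tibble ([usual_intake()]), or any tibble with
#'   `resp_id` and `usual`.
#' @param respondents Respondent tibble; replicate-weight columns are those
#'   matching `rep_prefix`.
#' @param ai_table AI reference.
#' @param grouping Grouping definition ([default_grouping()]).
#' @param rep_prefix Prefix of the replicate-weight columns
#'   (default `"repw_"`).
#' @param ci_multiplier CI half-width in SE units (default 2).
#' @return Tibble of group summaries in the configured order.
#' @export
build_group_summaries <- function(usual, respondents, ai_table,
                                  grouping = default_grouping(),
                                  rep_prefix = "repw_",
                                  ci_multiplier = 2) {
  df <- dplyr::inner_join(respondents, usual[, c("resp_id", "usual")],
                          by = "resp_id")
  rep_cols <- grep(paste0("^", rep_prefix), names(df), value = TRUE)
  rows <- list()
  for (k in seq_len(nrow(grouping))) {
    g <- grouping[k, ]
    sel <- .group_members(df, g)
    if (!any(sel)) {
      inform(sprintf("group '%s' is empty; row omitted", g$group_label))
      next
    }
    sub <- df[sel, ]
    m <- weighted_mean(sub$usual, sub$weight)
    se <- if (length(rep_cols) >= 2) {
      jackknife_se(weighted_mean, sub$usual, sub$weight,
                   as.matrix(sub[, rep_cols]))
    } else {
      stats::sd(sub$usual) / sqrt(nrow(sub))
    }
    ci <- confidence_interval(m, se, ci_multiplier)
    q <- weighted_quartiles(sub$usual, sub$weight)
    att <- ai_attainment(sub$usual, sub, ai_table)
    rows[[length(rows) + 1]] <- tibble::tibble(
      group_label = g$group_label,
      n = nrow(sub),
      pop_equivalent = sum(sub$weight),
      mean = round(m, 2), se = round(se, 2),
      ci_low = round(ci[["low"]], 2), ci_high = round(ci[["high"]], 2),
      q_min = round(q[["min"]], 2), q1 = round(q[["q1"]], 2),
      median = round(q[["median"]], 2), q3 = round(q[["q3"]], 2),
      q_max = round(q[["max"]], 2),
      ai = att$ai,
      pct_at_or_above_ai = att$pct_at_or_above,
      n_at_or_above_ai = att$n_at_or_above,
      pop_equivalent_at_or_above_ai = att$pop_equivalent_at_or_above)
  }
  dplyr::bind_rows(rows)
}
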