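# Food-source analysis: per-food-group contribution to total nutrient
# intake, per-consumer means, and top-N rankings. Source analyses use day-1
# reported intakes (not usual intakes), so rankings reflect consumption days.

#' Food-group contributions to total nutrient intake
#'
#' Attributes every day-1 intake event to its food group (2-, 3- or 5-digit
#' prefix level) and computes each group's weighted share of total
#' population intake, the weighted mean intake among that group's consumers,
#' and the unweighted consumer count. Ranks are assigned by descending
#' share; ties break by ascending group code.
#'
#' @param events Intake events; only `day == day_use` rows are analysed.
#' @param db Compiled nutrient database.
#' @param respondents Respondent tibble (`resp_id`, `weight`, demographics).
#' @param filter Optional logical vector over `respondents`, or a function
#'   of the respondent tibble returning one (e.g. a sex/age band selector).
#' @param level Grouping level: 2, 3 (default) or 5 digits.
#' @param day_use Which recall day to analyse (default 1).
#' @param nutrient Database column (default `"choline"`).
#' @return Tibble of contribution records: `group_code`, `n_consumers`,
#'   `per_consumer_mean` (mg/day), `pct_of_total`, `rank`. Shares sum to 100
#'   over all groups with any intake.
#' @export
group_contributions <- function(events, db, respondents, filter = NULL,
                                level = 3, day_use = 1,
                                nutrient = "choline") {
  stopifnot(level %in% c(2, 3, 5))
  keep <- if (is.null(filter)) {
    rep(TRUE, nrow(respondents))
  } else if (is.function(filter)) {
    filter(respondents)
  } else {
    filter
  }
  resp <- respondents[keep, ]
  if (nrow(resp) == 0) {
    inform("empty respondent filter; no contributions to report")
    return(tibble::tibble(group_code = character(), n_consumers = integer(),
                          per_consumer_mean = double(),
                          pct_of_total = double(), rank = integer()))
  }
  ev <- events[events$day == day_use & events$resp_id %in% resp$resp_id, ]
  idx <- match(ev$food_id, db$food_id)
  if (any(is.na(idx))) {
    abort(sprintf("unresolvable food id(s): %s",
                  paste(unique(ev$food_id[is.na(idx)]), collapse = ", ")),
          class = "cholinedb_compilation_error")
  }
  grp_col <- paste0("group", level)
  per <- tibble::tibble(resp_id = ev$resp_id,
                        group_code = db[[grp_col]][idx],
                        mg = ev$grams * db[[nutrient]][idx] / 100) %>%
    dplyr::group_by(.data$resp_id, .data$group_code) %>%
    dplyr::summarise(mg = sum(.data$mg), .groups = "drop") %>%
    dplyr::inner_join(resp[, c("resp_id", "weight")], by = "resp_id")
  total_mg <- sum(per$mg * per$weight)
  out <- per %>%
    dplyr::group_by(.data$group_code) %>%
    dplyr::summarise(
      n_consumers = sum(.data$mg > 0),
      per_consumer_mean = if (any(.data$mg > 0)) {
        weighted_mean(.data$mg[.data$mg > 0], .data$weight[.data$mg > 0])
      } else {
        NA_real_
      },
      attributed_mg = sum(.data$mg * .data$weight),
      .groups = "drop") %>%
    dplyr::mutate(pct_of_total = 100 * .data$attributed_mg / total_mg) %>%
    dplyr::arrange(dplyr::desc(.data$pct_of_total), .data$group_code) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::select("group_code", "n_consumers", "per_consumer_mean",
                  "pct_of_total", "rank")
  out
}

#' Truncate contribution records to the top N groups
#'
#' @param records Contribution records ([group_contributions()]).
#' @param n How many top-ranked groups to keep (default 20; clamped to the
#'   number available).
#' @return List: `records` (the first `n` by rank) and `cumulative_pct`
#'   (their summed share of total intake, rounded to 2 decimals).
#' @export
top_n_sources <- function(records, n = 20) {
  kept <- records[order(records$rank), ][seq_len(min(n, nrow(records))), ]
  list(records = kept, cumulative_pct = round(sum(kept$pct_of_total), 2))
}
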