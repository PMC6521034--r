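#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr %>%
NULL

# Canonical column names used internally for each table kind.  File headers
# are mapped onto these via a dialect config (see `default_dialect()`), so
# AUSNUT/USDA-style exports can be adapted without code changes.
.food_cols <- c("food_id", "name", "moisture", "protein", "energy",
                "choline", "betaine")
.donor_cols <- c("donor_id", "donor_name", "moisture", "protein",
                 "choline", "betaine", "donor_source")
.ai_cols <- c("group_label", "sex", "age_min", "age_max", "life_stage", "ai")
.recipe_cols <- c("recipe_id", "ingredient_id", "raw_weight",
                  "weight_change_factor", "retention")

#' Default file dialect
#'
#' The dialect maps canonical column names to the headers found in a file
#' (identity by default) for each table kind. Files are comma-separated,
#' UTF-8, one header row; empty cells denote missing nutrient values, which
#' are kept distinct from literal zeros.
#'
#' @param food,donor,ai,recipe Named character vectors overriding the
#'   identity mapping, `c(canonical = "file header")`.
#' @return A list of per-table mappings.
#' @export
default_dialect <- function(food = NULL, donor = NULL, ai = NULL,
                            recipe = NULL) {
  ident <- function(cols, override) {
    m <- stats::setNames(cols, cols)
    if (!is.null(override)) m[names(override)] <- override
    m
  }
  list(food = ident(.food_cols, food),
       donor = ident(.donor_cols, donor),
       ai = ident(.ai_cols, ai),
       recipe = ident(.recipe_cols, recipe))
}

#' Read a dialect config from a YAML file
#'
#' @param path Path to a YAML file with optional `food`, `donor`, `ai`,
#'   `recipe` sections, each a `canonical: header` mapping.
#' @return A dialect list as produced by [default_dialect()].
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_map <- function(x) if (is.null(x)) NULL else unlist(x)
  default_dialect(food = as_map(cfg$food), donor = as_map(cfg$donor),
                  ai = as_map(cfg$ai), recipe = as_map(cfg$recipe))
}

# Read a CSV and rename file headers to canonical names. `required` are the
# canonical columns that must resolve; others are optional and filled with NA.
.read_mapped_csv <- function(path, mapping, required, numeric_cols) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cholinedb_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE,
                         show_col_types = FALSE)
  missing <- setdiff(unname(mapping[required]), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cholinedb_schema_error")
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in names(mapping)) {
    header <- mapping[[canon]]
    out[[canon]] <- if (header %in% names(raw)) raw[[header]] else NA_character_
  }
  for (col in intersect(numeric_cols, names(out))) {
    vals <- out[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s' at row(s): %s",
                    col, paste(bad, collapse = ", ")),
            class = "cholinedb_parse_error")
    }
    out[[col]] <- num
  }
  out
}

# Validate an 8-digit food code vector; returns invisibly or aborts with the
# offending row indices.
.check_food_id <- function(ids, what = "food_id") {
  bad <- which(is.na(ids) | !grepl("^[0-9]{8}$", ids))
  if (length(bad) > 0) {
    abort(sprintf("malformed %s (need 8 digits) at row(s): %s",
                  what, paste(bad, collapse = ", ")),
          class = "cholinedb_parse_error")
  }
  invisible(ids)
}

# Derive the 2/3/5-digit group-prefix codes from 8-digit food codes.
.add_group_codes <- function(df) {
  df$group2 <- substr(df$food_id, 1, 2)
  df$group3 <- substr(df$food_id, 1, 3)
  df$group5 <- substr(df$food_id, 1, 5)
  df
}

.check_composition <- function(df, what = "food table") {
  with_val <- function(col) !is.na(df[[col]])
  if (any(with_val("moisture") & (df$moisture < 0 | df$moisture > 100))) {
    abort(sprintf("%s: moisture must lie in [0, 100] g/100 g", what),
          class = "cholinedb_validation_error")
  }
  if (any(with_val("protein") & df$protein < 0)) {
    abort(sprintf("%s: protein must be >= 0", what),
          class = "cholinedb_validation_error")
  }
  if ("choline" %in% names(df) && any(with_val("choline") & df$choline < 0)) {
    abort(sprintf("%s: choline must be >= 0 when present", what),
          class = "cholinedb_validation_error")
  }
  invisible(df)
}

#' Read a target food table
#'
#' Reads an AUSNUT-style food list: 8-digit food codes with per-100 g
#' moisture, protein and energy, and optionally existing choline/betaine
#' values. The 2/3/5-digit food-group codes are derived as literal prefixes
#' of the food code.
#'
#' @param path CSV file path.
#' @param dialect Dialect list from [default_dialect()] or [read_dialect()].
#' @return A tibble of food records with derived `group2`/`group3`/`group5`
#'   columns and empty provenance columns (`source`, `confidence`,
#'   `unmatched_zero`, `donor_id`) ready for compilation.
#' @export
read_food_table <- function(path, dialect = default_dialect()) {
  df <- .read_mapped_csv(path, dialect$food, required = c("food_id", "name"),
                         numeric_cols = c("moisture", "protein", "energy",
                                          "choline", "betaine"))
  if (nrow(df) > 0) .check_food_id(df$food_id)
  df <- .add_group_codes(df)
  .check_composition(df)
  df$source <- ifelse(is.na(df$choline), NA_character_, "analytical")
  df$confidence <- NA_character_
  df$unmatched_zero <- FALSE
  df$donor_id <- NA_character_
  df[, c("food_id", "name", "group2", "group3", "group5", "moisture",
         "protein", "energy", "choline", "betaine", "source", "confidence",
         "unmatched_zero", "donor_id")]
}

#' Read a donor nutrient table
#'
#' Reads a USDA-style donor table holding choline (and optionally betaine)
#' values per 100 g along with the moisture and protein composition needed
#' for borrowing adjustments.
#'
#' @inheritParams read_food_table
#' @return A tibble of donor records.
#' @export
read_donor_table <- function(path, dialect = default_dialect()) {
  df <- .read_mapped_csv(path, dialect$donor,
                         required = c("donor_id", "choline"),
                         numeric_cols = c("moisture", "protein", "choline",
                                          "betaine"))
  .check_composition(df, what = "donor table")
  df
}

#' Read a recipe file
#'
#' Reads an FSANZ-style recipe file in long form: one row per ingredient with
#' its raw weight in grams, the recipe's total weight-change (yield) factor
#' repeated on each row, and an optional per-ingredient retention factor
#' (defaulting to 1, i.e. no cooking loss).
#'
#' @inheritParams read_food_table
#' @return A named list of recipe specs, each a list with `recipe_id`,
#'   `ingredients` (tibble of `food_id`, `raw_weight`, `retention`) and
#'   `weight_change_factor`. Ingredient order is preserved.
#' @export
read_recipe_file <- function(path, dialect = default_dialect()) {
  df <- .read_mapped_csv(path, dialect$recipe,
                         required = c("recipe_id", "ingredient_id",
                                      "raw_weight", "weight_change_factor"),
                         numeric_cols = c("raw_weight",
                                          "weight_change_factor",
                                          "retention"))
  if (nrow(df) == 0) return(structure(list(), names = character()))
  .check_food_id(df$recipe_id, "recipe_id")
  .check_food_id(df$ingredient_id, "ingredient_id")
  df$retention[is.na(df$retention)] <- 1
  recipes <- split(df, factor(df$recipe_id, levels = unique(df$recipe_id)))
  out <- lapply(recipes, function(r) {
    wcf <- unique(r$weight_change_factor)
    if (length(wcf) != 1) {
      abort(sprintf("recipe %s: inconsistent weight-change factor", r$recipe_id[1]),
            class = "cholinedb_validation_error")
    }
    recipe_spec(recipe_id = r$recipe_id[1],
                ingredients = tibble::tibble(food_id = r$ingredient_id,
                                             raw_weight = r$raw_weight,
                                             retention = r$retention),
                weight_change_factor = wcf)
  })
  out
}

#' Construct a recipe spec
#'
#' @param recipe_id 8-digit food code of the composite food.
#' @param ingredients Tibble with `food_id`, `raw_weight` (g, > 0) and
#'   optionally `retention` (fraction in (0, 1], default 1).
#' @param weight_change_factor Ratio of cooked to raw total weight, > 0.
#' @return A validated recipe spec (list).
#' @export
recipe_spec <- function(recipe_id, ingredients, weight_change_factor) {
  if (!is.numeric(weight_change_factor) || length(weight_change_factor) != 1 ||
      is.na(weight_change_factor) || weight_change_factor <= 0) {
    abort(sprintf("recipe %s: weight-change factor must be a positive ratio",
                  recipe_id),
          class = "cholinedb_validation_error")
  }
  if (!"retention" %in% names(ingredients)) ingredients$retention <- 1
  if (nrow(ingredients) < 1) {
    abort(sprintf("recipe %s: needs at least one ingredient", recipe_id),
          class = "cholinedb_validation_error")
  }
  if (any(is.na(ingredients$raw_weight) | ingredients$raw_weight <= 0)) {
    abort(sprintf("recipe %s: raw weights must be > 0", recipe_id),
          class = "cholinedb_validation_error")
  }
  if (any(is.na(ingredients$retention) | ingredients$retention <= 0 |
          ingredients$retention > 1)) {
    abort(sprintf("recipe %s: retention factors must lie in (0, 1]", recipe_id),
          class = "cholinedb_validation_error")
  }
  list(recipe_id = recipe_id,
       ingredients = ingredients[, c("food_id", "raw_weight", "retention")],
       weight_change_factor = weight_change_factor)
}

#' Read an Adequate Intake reference table
#'
#' One row per (sex, age band, life stage) combination with the AI in mg/day.
#' Age bands are closed intervals in whole years (a 2-3 band covers ages
#' 2 <= age <= 3). Bands must not overlap within a sex/life-stage stratum.
#'
#' @inheritParams read_food_table
#' @return A tibble of AI reference rows.
#' @export
read_ai_reference <- function(path, dialect = default_dialect()) {
  df <- .read_mapped_csv(path, dialect$ai,
                         required = c("sex", "age_min", "age_max", "ai"),
                         numeric_cols = c("age_min", "age_max", "ai"))
  df$life_stage[is.na(df$life_stage)] <- "none"
  validate_ai_reference(df)
}

#' Validate an AI reference table
#'
#' @param df Tibble with columns `group_label`, `sex`, `age_min`, `age_max`,
#'   `life_stage`, `ai`.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_ai_reference <- function(df) {
  if (any(is.na(df$ai) | df$ai <= 0)) {
    abort("AI values must be > 0", class = "cholinedb_validation_error")
  }
  if (any(df$age_min > df$age_max)) {
    abort("AI reference: age_min must be <= age_max",
          class = "cholinedb_validation_error")
  }
  if (!all(df$sex %in% c("male", "female", "any"))) {
    abort("AI reference: sex must be male/female/any",
          class = "cholinedb_validation_error")
  }
  if (!all(df$life_stage %in% c("none", "pregnant", "lactating"))) {
    abort("AI reference: life_stage must be none/pregnant/lactating",
          class = "cholinedb_validation_error")
  }
  df
}

#' Look up the Adequate Intake for one respondent
#'
#' Life-stage rows (pregnant, lactating) take precedence over plain sex/age
#' rows. A respondent matching no row returns `NA` (such respondents are
#' excluded from AI-attainment summaries, with a notice).
#'
#' @param age Age in whole years at interview.
#' @param sex `"male"` or `"female"`.
#' @param life_stage `"none"`, `"pregnant"` or `"lactating"`.
#' @param ai_table AI reference tibble ([read_ai_reference()]).
#' @return AI in mg/day, or `NA_real_` when no band covers the respondent.
#' @export
lookup_ai <- function(age, sex, life_stage = "none", ai_table) {
  sex_ok <- ai_table$sex == sex | ai_table$sex == "any"
  age_ok <- ai_table$age_min <= age & age <= ai_table$age_max
  if (life_stage != "none") {
    hit <- which(sex_ok & age_ok & ai_table$life_stage == life_stage)
    if (length(hit) > 1) {
      abort("overlapping AI reference rows for one respondent",
            class = "cholinedb_config_error")
    }
    if (length(hit) == 1) return(ai_table$ai[hit])
  }
  hit <- which(sex_ok & age_ok & ai_table$life_stage == "none")
  if (length(hit) > 1) {
    abort("overlapping AI reference rows for one respondent",
          class = "cholinedb_config_error")
  }
  if (length(hit) == 0) return(NA_real_)
  ai_table$ai[hit]
}

#' Write a compiled nutrient database to CSV
#'
#' Output uses explicit unit-bearing headers (`choline_mg_100g`,
#' `betaine_mg_100g`) plus provenance columns `source`, `confidence`,
#' `unmatched_zero_flag` and `donor_id`. Missing values are written as empty
#' cells, keeping borrowed zeros distinguishable from absent values.
#'
#' @param db Compiled database tibble (as built by [compile_database()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nutrient_db <- function(db, path) {
  out <- db
  names(out)[names(out) == "choline"] <- "choline_mg_100g"
  names(out)[names(out) == "betaine"] <- "betaine_mg_100g"
  names(out)[names(out) == "unmatched_zero"] <- "unmatched_zero_flag"
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a compiled nutrient database written by [write_nutrient_db()]
#'
#' @param path CSV path.
#' @return The compiled database tibble, field-for-field equal to what was
#'   written.
#' @export
read_nutrient_db <- function(path) {
  df <- readr::read_csv(path, na = "", progress = FALSE,
                        col_types = readr::cols(
                          food_id = "c", name = "c", group2 = "c",
                          group3 = "c", group5 = "c", moisture = "d",
                          protein = "d", energy = "d",
                          choline_mg_100g = "d", betaine_mg_100g = "d",
                          source = "c", confidence = "c",
                          unmatched_zero_flag = "l", donor_id = "c"))
  names(df)[names(df) == "choline_mg_100g"] <- "choline"
  names(df)[names(df) == "betaine_mg_100g"] <- "betaine"
  names(df)[names(df) == "unmatched_zero_flag"] <- "unmatched_zero"
  df
}
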