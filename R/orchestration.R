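# End-to-end runner: simulate (or load) inputs, compile the database,
# estimate usual intakes, build group summaries, rank food sources and fit
# the per-group models, writing each stage's table and one reproducibility
# manifest.

#' Default pipeline configuration
#'
#' @param seed Top-level seed; all stage randomness derives from it.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param n_foods,coverage_fraction,n_recipes Food-database scenario.
#' @param n_respondents,sigma2_between,sigma2_within,n_replicates,day2_fraction
#'   Survey scenario.
#' @param qa_fraction Verification-sample fraction for the QA stage.
#' @param top_n Number of top food sources to keep.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cholinedb_run_"),
                            n_foods = 500, coverage_fraction = 0.9751,
                            n_recipes = 10, n_respondents = 2000,
                            sigma2_between = 400, sigma2_within = 1600,
                            n_replicates = 30, day2_fraction = 0.85,
                            qa_fraction = 0.10, top_n = 20) {
  as.list(environment())
}

.validate_config <- function(config) {
  defaults <- pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "cholinedb_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  num_fields <- setdiff(names(cfg), "out_dir")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]])) {
      abort(sprintf("config field '%s' must be a single number", f),
            class = "cholinedb_config_error")
    }
  }
  if (cfg$coverage_fraction <= 0 || cfg$coverage_fraction > 1 ||
      cfg$qa_fraction <= 0 || cfg$qa_fraction > 1 ||
      cfg$day2_fraction < 0 || cfg$day2_fraction > 1) {
    abort("config fractions must lie in (0, 1]",
          class = "cholinedb_config_error")
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "cholinedb_stage_error", parent = e)
  })
}

#' Run the full compilation and intake-estimation pipeline
#'
#' Stages, in order: `simulate` (synthetic inputs from the seed), `compile`
#' (nutrient database + QA + coverage), `intakes` (daily and usual
#' intakes), `summarise` (Table-1-style group summaries), `sources` (top-N
#' food groups), `models` (per-group regressions and their ranking). Each
#' stage writes a CSV under `out_dir`; a JSON manifest with the config
#' snapshot and file digests is written last. Any stage failure aborts with
#' the stage name.
#'
#' @param config List of overrides accepted by [pipeline_config()].
#' @return List with every stage's in-memory result plus `manifest`.
#' @export
run_all <- function(config = list()) {
  cfg <- .validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) {
    readr::write_csv(df, file.path(cfg$out_dir, f), na = "",
                     progress = FALSE)
    f
  }
  files <- character(0)

  sim <- .stage("simulate", {
    fooddb <- generate_food_db(cfg$n_foods, cfg$coverage_fraction,
                               cfg$n_recipes, seed = cfg$seed)
    list(fooddb = fooddb)
  })
  db <- .stage("compile", {
    compile_database(sim$fooddb$food, sim$fooddb$donors, sim$fooddb$matches,
                     sim$fooddb$recipes)
  })
  qa <- .stage("compile", qa_checks(db, fraction = cfg$qa_fraction,
                                    seed = cfg$seed,
                                    recipes = sim$fooddb$recipes))
  cov <- coverage_stats(db)
  files <- c(files, w(db %>% dplyr::rename(choline_mg_100g = "choline",
                                           betaine_mg_100g = "betaine",
                                           unmatched_zero_flag = "unmatched_zero"),
                      "compiled_db.csv"))

  survey <- .stage("simulate", {
    generate_survey(db, cfg$n_respondents, cfg$sigma2_between,
                    cfg$sigma2_within, cfg$day2_fraction,
                    cfg$n_replicates, seed = cfg$seed + 1L)
  })
  intakes <- .stage("intakes", {
    daily <- daily_intake(survey$events, db, survey$design)
    comp <- fit_variance_components(daily, survey$respondents)
    usual <- usual_intake(daily, comp, survey$respondents)
    list(daily = daily, components = comp, usual = usual)
  })
  files <- c(files, w(intakes$usual, "usual_intakes.csv"))

  ai_table <- default_ai_reference()
  summaries <- .stage("summarise", {
    build_group_summaries(intakes$usual, survey$respondents, ai_table)
  })
  files <- c(files, w(summaries, "group_summaries.csv"))

  sources <- .stage("sources", {
    contrib <- group_contributions(survey$events, db, survey$respondents)
    top_n_sources(contrib, cfg$top_n)
  })
  files <- c(files, w(sources$records, "top_sources.csv"))

  models <- .stage("models", {
    fits <- fit_group_models(survey$events, db, survey$respondents,
                             intakes$usual)
    list(fits = fits, ranking = rank_models(fits))
  })
  files <- c(files, w(models$ranking, "model_ranking.csv"))

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    coverage = cov,
    outputs = as.list(tools::md5sum(file.path(cfg$out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(db = db, qa = qa, coverage = cov, survey = survey,
       intakes = intakes, summaries = summaries, sources = sources,
       models = models, manifest = manifest)
}
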