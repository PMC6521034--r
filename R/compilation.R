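# Building the compiled nutrient database: value borrowing with
# moisture/protein adjustment and confidence coding, recipe composites with
# weight-change and retention factors, the unmatched-zero policy, and QA.

#' Moisture (dry-matter) adjustment of a borrowed nutrient value
#'
#' Rescales a donor value to the target food's dry-matter fraction,
#' following the INFOODS food-matching convention:
#' `adjusted = value * (100 - moisture_tgt) / (100 - moisture_src)`.
#' Appropriate for water-soluble components such as choline and betaine.
#'
#' @param value Donor nutrient value, mg/100 g, >= 0.
#' @param moisture_src Donor moisture, g/100 g, < 100.
#' @param moisture_tgt Target moisture, g/100 g, < 100.
#' @return Adjusted value in mg/100 g. Equals `value` when moistures agree.
#' @export
moisture_adjust <- function(value, moisture_src, moisture_tgt) {
  if (any(value < 0)) {
    abort("nutrient value must be >= 0", class = "cholinedb_domain_error")
  }
  if (any(moisture_src >= 100) || any(moisture_tgt >= 100)) {
    abort("moisture must be < 100 g/100 g (dry matter would vanish)",
          class = "cholinedb_domain_error")
  }
  value * (100 - moisture_tgt) / (100 - moisture_src)
}

#' Protein adjustment of a borrowed nutrient value
#'
#' Proportional rescale by the protein ratio,
#' `adjusted = value * protein_tgt / protein_src`, for nutrient fractions
#' associated with the protein matrix.
#'
#' @param value Donor nutrient value, mg/100 g.
#' @param protein_src Donor protein, g/100 g, > 0.
#' @param protein_tgt Target protein, g/100 g.
#' @return Adjusted value in mg/100 g.
#' @export
protein_adjust <- function(value, protein_src, protein_tgt) {
  if (any(protein_src <= 0)) {
    abort("protein adjustment not applicable: donor protein is 0",
          class = "cholinedb_adjustment_error")
  }
  value * protein_tgt / protein_src
}

#' Assign a food-match confidence code
#'
#' A-D rubric in the spirit of the FAO/INFOODS matching guidelines (A = high
#' quality exact match, D = weak match). The rubric is fixed here since the
#' guideline table itself is applied by judgement in practice:
#' A - species, part/cut and processing all match, no adjustment needed;
#' B - all three match but an adjustment was needed, or exactly one was
#'     relaxed; C - two relaxed; D - otherwise.
#' Relaxing any flag never improves the code.
#'
#' @param same_species,same_part_or_cut,same_processing Logical match flags.
#' @param adjustment_needed Logical; was a compositional adjustment applied?
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
assign_confidence <- function(same_species, same_part_or_cut,
                              same_processing, adjustment_needed) {
  n_relaxed <- (!same_species) + (!same_part_or_cut) + (!same_processing)
  if (n_relaxed == 0) {
    if (adjustment_needed) "B" else "A"
  } else if (n_relaxed == 1) {
    "B"
  } else if (n_relaxed == 2) {
    "C"
  } else {
    "D"
  }
}

#' Borrow a nutrient value from a donor food
#'
#' Applies the policy's adjustment (none, moisture, or protein) to the
#' donor's choline value, carries betaine through under the same adjustment
#' when present, and grades the match with [assign_confidence()].
#'
#' @param target One row of a food table (list or one-row tibble) with
#'   `food_id`, `moisture`, `protein`.
#' @param donor One donor record with `donor_id`, `moisture`, `protein`,
#'   `choline` and optionally `betaine`.
#' @param policy List: `adjustment` (`"none"`, `"moisture"`, `"protein"`),
#'   match flags `same_species`, `same_part_or_cut`, `same_processing`
#'   (default `TRUE`), `fallback_to_moisture` (default `TRUE`; used when a
#'   protein adjustment is not applicable), and optionally
#'   `energy_ratio_tol` checked against `target$energy` / `donor$energy`.
#' @return A match-result list: `target_id`, `donor_id`, `adjustment`,
#'   `confidence`, `adjusted_choline`, `adjusted_betaine` (`NA` when the
#'   donor lacks betaine), `rationale`.
#' @export
borrow_value <- function(target, donor, policy = list()) {
  adj <- policy$adjustment %||% "moisture"
  flags <- list(same_species = policy$same_species %||% TRUE,
                same_part_or_cut = policy$same_part_or_cut %||% TRUE,
                same_processing = policy$same_processing %||% TRUE)
  if (is.na(donor$choline)) {
    abort("donor has no choline value", class = "cholinedb_match_error")
  }
  if (!is.null(policy$energy_ratio_tol) &&
      !is.null(target$energy) && !is.null(donor$energy) &&
      !is.na(target$energy) && !is.na(donor$energy) && donor$energy > 0) {
    ratio <- target$energy / donor$energy
    tol <- policy$energy_ratio_tol
    if (ratio > 1 + tol || ratio < 1 / (1 + tol)) {
      abort(sprintf("match rejected: energy ratio %.3f outside tolerance %.2f",
                    ratio, tol),
            class = "cholinedb_match_error")
    }
  }
  apply_adj <- function(value, kind) {
    switch(kind,
           none = value,
           moisture = moisture_adjust(value, donor$moisture, target$moisture),
           protein = protein_adjust(value, donor$protein, target$protein),
           abort(sprintf("unknown adjustment '%s'", kind),
                 class = "cholinedb_config_error"))
  }
  kind <- adj
  if (adj == "protein" && (is.na(donor$protein) || donor$protein <= 0)) {
    if (isTRUE(policy$fallback_to_moisture %||% TRUE)) {
      kind <- "moisture"
    } else {
      abort("protein adjustment impossible and no fallback allowed",
            class = "cholinedb_match_error")
    }
  }
  # no-op adjustments (equal composition) still count as "needed" only when
  # the composition actually differs
  needed <- switch(kind,
                   none = FALSE,
                   moisture = !isTRUE(all.equal(donor$moisture, target$moisture)),
                   protein = !isTRUE(all.equal(donor$protein, target$protein)))
  choline <- apply_adj(donor$choline, if (needed) kind else "none")
  betaine <- if (!is.null(donor$betaine) && !is.na(donor$betaine)) {
    apply_adj(donor$betaine, if (needed) kind else "none")
  } else {
    NA_real_
  }
  conf <- assign_confidence(flags$same_species, flags$same_part_or_cut,
                            flags$same_processing, needed)
  list(target_id = target$food_id, donor_id = donor$donor_id,
       adjustment = if (needed) kind else "none", confidence = conf,
       adjusted_choline = choline, adjusted_betaine = betaine,
       rationale = sprintf("borrowed from %s (%s adjustment, confidence %s)",
                           donor$donor_id, if (needed) kind else "no", conf))
}

#' Compute a composite food's nutrient value from a recipe
#'
#' Sums ingredient nutrient masses (raw weight x value/100 x retention) and
#' divides by the cooked mass, `weight_change_factor x total raw weight`,
#' re-expressing the result per 100 g of the cooked composite.
#'
#' @param recipe A recipe spec ([recipe_spec()]).
#' @param db Compiled database tibble; ingredient `food_id`s must resolve to
#'   rows with a non-missing value for `nutrient`.
#' @param nutrient Column to compute (default `"choline"`).
#' @return Composite value in mg/100 g.
#' @export
compute_recipe <- function(recipe, db, nutrient = "choline") {
  idx <- match(recipe$ingredients$food_id, db$food_id)
  missing <- recipe$ingredients$food_id[is.na(idx) | is.na(db[[nutrient]][idx])]
  if (length(missing) > 0) {
    abort(sprintf("recipe %s: unresolved ingredient(s): %s", recipe$recipe_id,
                  paste(missing, collapse = ", ")),
          class = "cholinedb_compilation_error")
  }
  w <- recipe$ingredients$raw_weight
  vals <- db[[nutrient]][idx]
  ret <- recipe$ingredients$retention
  100 * sum(w * vals / 100 * ret) / (recipe$weight_change_factor * sum(w))
}

# Order recipes so every nested recipe ingredient is computed before its
# parent; cycles are hard errors naming the cycle.
.topo_order_recipes <- function(recipes) {
  ids <- vapply(recipes, `[[`, character(1), "recipe_id")
  deps <- lapply(recipes, function(r) {
    intersect(r$ingredients$food_id, ids)
  })
  names(deps) <- ids
  order <- character(0)
  state <- stats::setNames(rep("new", length(ids)), ids)
  visit <- function(id, path) {
    if (state[[id]] == "done") return()
    if (state[[id]] == "active") {
      cyc <- c(path[which(path == id):length(path)], id)
      abort(sprintf("cyclic recipe nesting: %s", paste(cyc, collapse = " -> ")),
            class = "cholinedb_cycle_error")
    }
    state[[id]] <<- "active"
    for (d in deps[[id]]) visit(d, c(path, id))
    state[[id]] <<- "done"
    order <<- c(order, id)
  }
  for (id in ids) visit(id, character(0))
  recipes[match(order, ids)]
}

#' Resolve all recipes against a database
#'
#' Computes every recipe composite in topological order (nested recipes
#' first) and writes the results into the database with `source = "recipe"`.
#' Betaine is computed alongside choline when all ingredients carry betaine.
#'
#' @param db Compiled database tibble containing rows for every recipe id.
#' @param recipes List of recipe specs.
#' @return The updated database tibble.
#' @export
resolve_recipes <- function(db, recipes) {
  if (length(recipes) == 0) return(db)
  for (r in .topo_order_recipes(recipes)) {
    i <- match(r$recipe_id, db$food_id)
    if (is.na(i)) {
      abort(sprintf("recipe id %s not present in the food table", r$recipe_id),
            class = "cholinedb_compilation_error")
    }
    db$choline[i] <- compute_recipe(r, db, "choline")
    idx <- match(r$ingredients$food_id, db$food_id)
    if (all(!is.na(idx)) && all(!is.na(db$betaine[idx]))) {
      db$betaine[i] <- compute_recipe(r, db, "betaine")
    }
    db$source[i] <- "recipe"
    db$confidence[i] <- NA_character_
    db$unmatched_zero[i] <- FALSE
  }
  db
}

#' Apply the unmatched-zero policy
#'
#' Foods for which no value could be identified are recorded with choline 0,
#' `source = "unmatched_zero"` and a distinguishing flag, so these policy
#' zeros remain separable from true analytical zeros.
#'
#' @param db Compiled database tibble.
#' @param unmatched Character vector of food ids still lacking a value.
#' @return The updated database tibble.
#' @export
apply_zero_policy <- function(db, unmatched) {
  if (length(unmatched) == 0) return(db)
  idx <- match(unmatched, db$food_id)
  if (any(is.na(idx))) {
    abort(sprintf("unmatched ids not in database: %s",
                  paste(unmatched[is.na(idx)], collapse = ", ")),
          class = "cholinedb_policy_error")
  }
  has_value <- !is.na(db$choline[idx])
  if (any(has_value)) {
    abort(sprintf("refusing to zero foods that already carry a value: %s",
                  paste(unmatched[has_value], collapse = ", ")),
          class = "cholinedb_policy_error")
  }
  db$choline[idx] <- 0
  db$source[idx] <- "unmatched_zero"
  db$unmatched_zero[idx] <- TRUE
  db
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Quality-assurance checks on a compiled database
#'
#' Rank-orders foods by value, applies per-group range checks, re-computes
#' every recipe a second time as a duplicate-calculation check, and draws a
#' seeded source-data-verification sample without replacement.
#'
#' @param db Compiled database tibble.
#' @param bounds Optional tibble with `group2`, `lower`, `upper` giving
#'   plausible per-group value ranges (mg/100 g); groups without a row fall
#'   back to `default_bound`.
#' @param default_bound Length-2 numeric, global `(lower, upper)` bound.
#' @param fraction Verification-sample fraction in (0, 1]; sample size is
#'   `round(fraction * nrow(db))`.
#' @param seed Integer seed making the verification sample reproducible.
#' @param recipes Optional recipe list for the duplicate-calculation check.
#' @param tol Absolute tolerance for duplicate-calculation agreement.
#' @return List: `ranked` (food ids, descending choline), `violations`
#'   (tibble of `food_id`, `value`, `lower`, `upper`), `duplicate_mismatches`
#'   (character vector of recipe ids), `verification_sample` (food ids).
#' @export
qa_checks <- function(db, bounds = NULL, default_bound = c(0, Inf),
                      fraction = 0.10, seed = 1L, recipes = list(),
                      tol = 1e-8) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]", class = "cholinedb_parameter_error")
  }
  valued <- db[!is.na(db$choline), ]
  ranked <- valued$food_id[order(-valued$choline, valued$food_id)]
  lo <- rep(default_bound[1], nrow(valued))
  hi <- rep(default_bound[2], nrow(valued))
  if (!is.null(bounds)) {
    bi <- match(valued$group2, bounds$group2)
    lo[!is.na(bi)] <- bounds$lower[bi[!is.na(bi)]]
    hi[!is.na(bi)] <- bounds$upper[bi[!is.na(bi)]]
  }
  viol <- valued$choline < lo | valued$choline > hi
  violations <- tibble::tibble(food_id = valued$food_id[viol],
                               value = valued$choline[viol],
                               lower = lo[viol], upper = hi[viol])
  dup <- character(0)
  for (r in recipes) {
    i <- match(r$recipe_id, db$food_id)
    if (!is.na(i) && !is.na(db$choline[i])) {
      again <- compute_recipe(r, db)
      if (!is.na(again) && abs(again - db$choline[i]) > tol) {
        dup <- c(dup, r$recipe_id)
      }
    }
  }
  n_sample <- round(fraction * nrow(db))
  sample_ids <- .with_seed(seed, sample(db$food_id, n_sample))
  list(ranked = ranked, violations = violations,
       duplicate_mismatches = dup, verification_sample = sample_ids)
}

#' Database coverage statistics
#'
#' Counts foods aligned with a genuine choline value (policy zeros for
#' unmatched foods are excluded) and foods carrying betaine.
#'
#' @param db Compiled database tibble.
#' @return List: `n_with_value`, `percent_of_total` (rounded to 2 decimals),
#'   `n_with_betaine`, `n_total`.
#' @export
coverage_stats <- function(db) {
  n_total <- nrow(db)
  n_value <- sum(!is.na(db$choline) & !db$unmatched_zero)
  list(n_with_value = n_value,
       percent_of_total = round(100 * n_value / n_total, 2),
       n_with_betaine = sum(!is.na(db$betaine)),
       n_total = n_total)
}

#' Compile the nutrient database
#'
#' End-to-end database build: borrow donor values for the supplied candidate
#' matches, resolve recipe composites, and zero out the remainder under the
#' unmatched-zero policy.
#'
#' @param food Food table ([read_food_table()]).
#' @param donors Donor table ([read_donor_table()]).
#' @param matches Tibble of candidate pairs: `target_id`, `donor_id`, and
#'   optional per-pair policy columns `adjustment`, `same_species`,
#'   `same_part_or_cut`, `same_processing`.
#' @param recipes Recipe list ([read_recipe_file()]).
#' @param policy Default borrowing policy (see [borrow_value()]).
#' @return The compiled database tibble; every food carries a value
#'   (analytical, borrowed, recipe, or flagged zero).
#' @export
compile_database <- function(food, donors, matches = NULL, recipes = list(),
                             policy = list()) {
  db <- food
  if (!is.null(matches) && nrow(matches) > 0) {
    for (k in seq_len(nrow(matches))) {
      m <- matches[k, ]
      ti <- match(m$target_id, db$food_id)
      di <- match(m$donor_id, donors$donor_id)
      if (is.na(ti) || is.na(di)) {
        abort(sprintf("match %s -> %s: unknown target or donor",
                      m$target_id, m$donor_id),
              class = "cholinedb_match_error")
      }
      p <- policy
      for (f in c("adjustment", "same_species", "same_part_or_cut",
                  "same_processing")) {
        if (f %in% names(m) && !is.na(m[[f]])) p[[f]] <- m[[f]]
      }
      res <- borrow_value(as.list(db[ti, ]), as.list(donors[di, ]), p)
      db$choline[ti] <- res$adjusted_choline
      db$betaine[ti] <- res$adjusted_betaine
      db$source[ti] <- "borrowed"
      db$confidence[ti] <- res$confidence
      db$donor_id[ti] <- res$donor_id
    }
  }
  db <- resolve_recipes(db, recipes)
  unmatched <- db$food_id[is.na(db$choline)]
  apply_zero_policy(db, unmatched)
}
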