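# Shared in-code fixtures: tiny tables written to tempfiles, a minimal
# compiled database, and leave-one-out replicate weights.

write_tmp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

tiny_food_csv <- function() {
  write_tmp_csv(c(
    "food_id,name,moisture,protein,energy,choline,betaine",
    "13102031,milk full fat,88,3.3,270,16.2,0.6",
    "28101001,egg poached,75,12.5,560,225,0.4",
    "20205007,beef stew,65,14,700,,"))
}

tiny_db <- function() {
  food <- read_food_table(tiny_food_csv())
  food$choline[3] <- 60
  food$source[3] <- "analytical"
  food
}

# respondents with d leave-one-out replicate-weight columns (delete-1
# groups of size one), used against brute-force jackknife oracles
loo_replicates <- function(n, weight = rep(1, n)) {
  rw <- vapply(seq_len(n), function(i) {
    w <- weight * n / (n - 1)
    w[i] <- 0
    w
  }, numeric(n))
  colnames(rw) <- paste0("repw_", seq_len(n))
  rw
}

simple_respondents <- function(n, age = 30, sex = "male", weight = 1) {
  tibble::tibble(resp_id = sprintf("R%05d", seq_len(n)),
                 age = rep_len(age, n), sex = rep_len(sex, n),
                 life_stage = "none", weight = rep_len(weight, n))
}
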