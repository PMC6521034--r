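#!/usr/bin/env Rscript
# Stage 4: design-based group summaries — weighted means, grouped-jackknife
# SEs, 95% CIs, weighted quartiles, population equivalents and AI
# attainment per reporting group.

suppressMessages(library(cholinedb))

respondents <- readr::read_csv("results/inputs/respondents.csv",
                               show_col_types = FALSE)
usual <- readr::read_csv("results/usual_intakes.csv", show_col_types = FALSE)
ai <- read_ai_reference("results/inputs/ai_reference.csv")

summaries <- suppressWarnings(
  build_group_summaries(usual, respondents, ai))
readr::write_csv(summaries, "results/group_summaries.csv")

total <- summaries[summaries$group_label == "Total", ]
cat(sprintf("population mean usual intake %.2f mg/day (SE %.2f, 95%% CI %.2f-%.2f)\n",
            total$mean, total$se, total$ci_low, total$ci_high))
low_ai <- summaries[!is.na(summaries$pct_at_or_above_ai) &
                      summaries$pct_at_or_above_ai < 10, ]
cat(sprintf("%d of %d groups with an AI have fewer than 10%% of respondents at or above it\n",
            nrow(low_ai), sum(!is.na(summaries$pct_at_or_above_ai))))
print(as.data.frame(summaries[, c("group_label", "n", "mean", "se",
                                  "pct_at_or_above_ai")]))
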