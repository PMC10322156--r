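#!/usr/bin/env Rscript

# Step 3 -- Random-Forest ABC scenario choice.
#
# Trains the scenario classifier on the reference table (42 statistics +
# linear-discriminant axes, 500 trees), reports its out-of-bag confusion
# and prior error, and classifies the pseudo-observed dataset from step 2
# (true scenario: Afr2Pulses-EurRecurring).
#
# Inputs:  results/reference_table.tsv, results/observed_stats.tsv
# Outputs: results/scenario_choice.json

suppressPackageStartupMessages(library(admixabc))

table <- read_reference_table("results/reference_table.tsv")
observed <- unlist(read.table("results/observed_stats.tsv", header = TRUE,
                              sep = "\t"))

set.seed(20260940L)
fit <- rf_scenario_fit(table, ntree = 500L)
choice <- rf_scenario_choice(fit, observed)

message("out-of-bag prior error: ", round(fit$prior_error, 3),
        " (random guessing among 4 scenarios: 0.75)")
message("selected scenario: ", choice$selected,
        sprintf(" (%d/%d votes, posterior probability %.2f)",
                round(choice$votes[choice$selected]), sum(choice$votes),
                choice$posterior_probability))
message("top-5 statistics by importance: ",
        paste(names(sort(choice$importance, decreasing = TRUE))[1:5],
              collapse = ", "))

jsonlite::write_json(list(
  selected = choice$selected,
  votes = as.list(choice$votes),
  posterior_probability = choice$posterior_probability,
  prior_error = fit$prior_error,
  confusion = as.data.frame(fit$confusion),
  importance = as.list(sort(choice$importance, decreasing = TRUE))),
  "results/scenario_choice.json", auto_unbox = TRUE, digits = NA)
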