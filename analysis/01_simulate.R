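#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study world and its mortality surveys.
#
# Generates a 20-district, 2014-2018 world with a 2017-18 crisis (defaults
# of `world_config()`), draws 60 SMART-style surveys (70% individual
# questionnaire, 30% aggregate), and writes the canonical input CSVs that
# the later stages read back.

library(crisismort)

seed <- 1L
out <- "results/inputs"

world <- generate_world(world_config(seed = stage_seed(seed, "simulate")))
print(world)

n_ind <- 42L
surveys <- c(
  generate_surveys(world, n_ind, questionnaire = "individual",
                   seed = stage_seed(seed, "surveys_individual")),
  generate_surveys(world, 60L - n_ind, questionnaire = "aggregate",
                   seed = stage_seed(seed, "surveys_aggregate")))
for (i in seq_along(surveys))
  surveys[[i]]$meta$survey_id <- sprintf("svy%03d", i)

write_world_csvs(world, surveys, out)
cat("Wrote input CSVs to", out, "\n")
cat("True most-likely excess (generator ground truth):",
    round(true_excess(world)$excess), "deaths over 2017-18\n")
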