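#!/usr/bin/env Rscript
# Stage 5 — select and fit the predictive mortality models.
#
# Joins household survey rows to recall-averaged, lag-shifted, categorized
# predictor values; screens candidate predictors by single-term
# cross-validated Dawid-Sebastiani score; brute-force searches all
# candidate subsets (10-fold CV on identical folds); shortlists the top
# 20%; confirms on an 80/20 survey-level holdout; and fits the final
# quasi-Poisson models (same specification for CDR and U5DR) with
# cluster-robust covariances.

library(crisismort)

seed <- stage_seed(1L, "model_selection")

surveys <- filter_eligible(read_surveys_csv("results/inputs"),
                           min_year = 2014)$eligible
panel <- read.csv("results/predictor_panel.csv", stringsAsFactors = FALSE)
districts <- read.csv("results/inputs/districts.csv", stringsAsFactors = FALSE)

md <- survey_model_data(surveys, panel, districts)
candidates <- c("admin_level", "conflict", "sam", "malaria", "measles")

screened <- screen_predictors(candidates, md, seed = seed)
cat("Screened-in candidates:", paste(screened, collapse = ", "), "\n")

lb <- brute_force_search(screened, md, seed = seed)
write.csv(lb, "results/model_leaderboard.csv", row.names = FALSE)
cat("Top of the leaderboard:\n"); print(head(lb, 5))

final <- select_model(shortlist(lb, 0.2), md, seed = seed)
cat("Selected model:", paste(final$terms, collapse = " + "),
    "| rule:", attr(final, "rule"), "\n")

fit_cdr <- fit_quasipoisson(md, final)
fit_u5dr <- fit_quasipoisson(md, model_spec("U5DR", final$terms))
print(fit_cdr)
print(coef_table(fit_cdr))
write.csv(coef_table(fit_cdr), "results/model_cdr_coefficients.csv",
          row.names = FALSE)
write.csv(coef_table(fit_u5dr), "results/model_u5dr_coefficients.csv",
          row.names = FALSE)
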