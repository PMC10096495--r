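#!/usr/bin/env Rscript
# Stage 2 — re-analyse the mortality surveys.
#
# Reads the survey CSVs, filters for eligibility (district-representative
# universe, clear frame, standard questionnaire, recall within the
# modelling period), and estimates CDR and U5DR per survey with
# cluster-robust intervals, writing a per-survey estimates table.

library(crisismort)

surveys <- read_surveys_csv("results/inputs")
elig <- filter_eligible(surveys, min_year = 2014)
cat(length(elig$eligible), "of", length(surveys), "surveys eligible;",
    nrow(elig$exclusions), "excluded\n")
if (nrow(elig$exclusions)) print(table(elig$exclusions$reason))

estimates <- survey_estimates_table(elig$eligible)
dir.create("results", showWarnings = FALSE)
write.csv(estimates, "results/survey_estimates.csv", row.names = FALSE)

cat(sprintf("Median CDR %.2f (range %.2f-%.2f) per 10,000 person-days\n",
            median(estimates$cdr), min(estimates$cdr), max(estimates$cdr)))
cat(sprintf("Median U5DR %.2f; median household size %.1f; proportion under 5 %.2f\n",
            median(estimates$u5dr), median(estimates$mean_hh_size),
            median(estimates$prop_under5)))
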