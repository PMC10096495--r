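#!/usr/bin/env Rscript
# Stage 4 — prepare the district-month predictor panel.
#
# Screens raw predictors for completeness (>= 70% of district-months),
# imputes missing cells with region-weighted means (weights 1 / 0.3),
# smooths the price series with a penalized spline (spar 0.3), and writes
# the wide analysis panel plus per-cell provenance.

library(crisismort)

raw <- read_predictors_csv("results/inputs/predictors_raw.csv")
districts <- read.csv("results/inputs/districts.csv", stringsAsFactors = FALSE)
region <- setNames(districts$region, districts$district)

prep <- prepare_panel(raw, region, smooth = "water_price")
cat("Retained predictors:", paste(prep$retained, collapse = ", "), "\n")
print(table(prep$provenance$provenance))

panel <- prep$panel
panel$month <- ym_format(panel$ym)
write.csv(panel, "results/predictor_panel.csv", row.names = FALSE)
write.csv(prep$provenance, "results/predictor_provenance.csv", row.names = FALSE)
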