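#!/usr/bin/env Rscript
# Stage 3 — reconstruct district-month population denominators.
#
# Projects each census-source anchor across 2014-2018 with 2.1%/yr growth
# and monthly net displacement flows, averages the sources by quality
# weight, and summarises displacement by reported reason.

library(crisismort)

anchors <- read_anchors_csv("results/inputs/census_anchors.csv")
flows <- read_flows_csv("results/inputs/displacement_flows.csv")

pop <- build_population_series(anchors, flows, c("2014-01", "2018-12"))
print(pop)
write.csv(as.data.frame(pop), "results/population.csv", row.names = FALSE)

disp <- displacement_summary(flows)
print(disp)
write.csv(disp, "results/displacement_summary.csv", row.names = FALSE)

cat(sprintf("National population: %.2fM (2014-01) -> %.2fM (2018-12)\n",
            sum(pop$pop[, 1]) / 1e6, sum(pop$pop[, ncol(pop$pop)]) / 1e6))
cat(sprintf("IDP/returnee proportion at end of period: %.1f%%\n",
            100 * weighted.mean(pop$prop_idp[, ncol(pop$pop)],
                                pop$pop[, ncol(pop$pop)])))
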