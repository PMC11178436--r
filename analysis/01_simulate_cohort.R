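#!/usr/bin/env Rscript
# Simulate the study cohort: 8 diploid L. minor ponds and 4 triploid
# L. japonica (M/M/T) ponds, 3-6 clonal samples each, spread over a
# 200 km region with spatially correlated drift, sequenced at ~60x and
# called with a diploid caller.  Writes the VCF + metadata + hidden
# truth used by the downstream analysis scripts.

suppressPackageStartupMessages(library(lemnapop))

out_dir <- "results/cohort"
spec <- cohort_spec(n_pops_sp1 = 8, n_pops_sp2 = 4,
                    samples_per_pop = c(3, 4, 5, 6),
                    n_sites = 5000, seed = 2024)
print(spec)

cohort <- simulate_cohort(spec)
paths <- write_cohort(cohort$table, cohort$truth, out_dir)

cat("\nCohort written to", out_dir, "\n")
print(cohort$table)
cat("samples per species:\n")
print(table(cohort$truth$samples$species))
cat("parent-fixed sites:", sum(cohort$truth$is_fixed), "of",
    length(cohort$truth$is_fixed), "\n")
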