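#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort (2 control, 3 two-week, 3 three-week
# virtual mice) and write every per-animal artifact - phase-resolved
# specific-ventilation NIfTIs, lung mask, CT, maneuver traces and ground
# truth - under results/cohort/.
#
# Finding to carry forward: group severities are ordered
# control < week2 < week3 by construction, and tumor burden tracks the
# severity draw, so downstream stages can test effect directions against
# known truth.

suppressPackageStartupMessages(library(xvlung))

seed <- 42L
out <- "results/cohort"
unlink(out, recursive = TRUE)

res <- generate_cohort(cohort_config(), seed = seed, out_dir = out)

tr <- res$truth
cat("Cohort written to", out, "\n")
cat(sprintf("%d animals; tumor burden by group (%%):\n", nrow(tr)))
print(round(tapply(tr$tumor_burden_pct, tr$group, mean), 2))
cat("Ground truth: results/cohort/ground_truth.csv\n")
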