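#!/usr/bin/env Rscript
# Stage 4: join the XV metrics, mechanics and ground-truth tumor counts
# into the study table and run the statistics battery: per-parameter
# one-way linear models with estimated marginal means and Tukey-adjusted
# pairwise contrasts, boxplot summaries, a Welch t-test on body weight,
# and Pearson correlations of every parameter against log10 tumor count.
#
# Finding: week3-vs-control contrasts are the large ones, and compliance
# correlates negatively with log10 tumor count while mean CT gray
# correlates positively.

suppressPackageStartupMessages(library(xvlung))

xv <- read.csv("results/xv_metrics.csv")
mech <- read.csv("results/mechanics.csv")
truth <- read.csv("results/cohort/ground_truth.csv")
study <- read.csv("results/cohort/study_table.csv")

tab <- merge(merge(xv, mech[, setdiff(names(mech), "group")],
                   by = "animal_id"),
             truth[, c("animal_id", "tumor_count", "tumor_burden_pct")],
             by = "animal_id")
tab$weight_g <- study$weight_g[match(tab$animal_id, study$animal_id)]

st <- run_cohort_stats(tab)
write.csv(st$comparisons, "results/comparisons.csv", row.names = FALSE)
write.csv(st$correlations, "results/correlations.csv", row.names = FALSE)
write.csv(st$summaries, "results/summaries.csv", row.names = FALSE)

wt <- two_sample_ttest(tab$weight_g[tab$group == "control"],
                       tab$weight_g[tab$group != "control"])
cat(sprintf("Weight, control vs tumor-bearing: t = %.2f, p = %.3f\n",
            wt$t, wt$p))

cat("\nCorrelations with log10 tumor count (tumor-bearing animals):\n")
print(st$correlations[order(st$correlations$p), ][1:8, ], digits = 3)

ctr <- st$comparisons[!is.na(st$comparisons$contrast), ]
sig <- ctr[!is.na(ctr$p_adj) & ctr$p_adj < 0.05 &
             ctr$contrast == "control - week3", ]
cat("\nParameters with control vs week3 contrast at p_adj < 0.05:\n")
print(sig[, c("parameter", "estimate", "p_adj")], digits = 3)
cat("\nTables written to results/{comparisons,correlations,summaries}.csv\n")
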