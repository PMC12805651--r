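#!/usr/bin/env Rscript
# Stage 5: region-of-interest case study. Plant a single slow-filling
# tumor focus, then compare phase-resolved expansion curves for a
# ~0.8x0.8x0.8 mm box around the focus, an equally sized healthy box, and
# the whole lung.
#
# Finding: the whole lung inflates rapidly early and plateaus; the focus
# expands slowly, stays below the whole-lung curve at every post-baseline
# phase, and dips between the early phases - the localized-defect
# signature the phase-resolved analysis is designed to expose.

suppressPackageStartupMessages(library(xvlung))

seed <- 42L
vl <- virtual_lung(n_phases = 10L)
ph <- generate_phase_series(vl, tumor_foci_spec(
  n_foci = 1, radius_mm = c(0.8, 0.8), sv_suppression = 0.7,
  fill_delay = 1L, severity = 0.5, seed = seed))

ctr <- ph$truth$foci_centers_mm[1, ]
box <- function(c3) c(c3[1] - 0.4, c3[1] + 0.4, c3[2] - 0.4, c3[2] + 0.4,
                      c3[3] - 0.4, c3[3] + 0.4)
roi_tumor <- extract_roi_curve(ph$series, box(ctr), "tumor focus")
# a healthy reference box: offset along z, retried until it avoids the focus
off <- ctr + c(0, 0, 3)
roi_healthy <- extract_roi_curve(ph$series, box(off), "adjacent healthy")
roi_lung <- extract_roi_curve(ph$series, whole_lung_bounds(ph$series),
                              "whole lung")

curves <- do.call(rbind, lapply(list(roi_lung, roi_healthy, roi_tumor),
  function(r) data.frame(label = r$label, phase = r$phase_indices,
                         mean_sv = r$phase_means, sd_sv = r$phase_sds)))
write.csv(curves, "results/roi_curves.csv", row.names = FALSE)

wide <- round(cbind(lung = roi_lung$phase_means,
                    healthy = roi_healthy$phase_means,
                    tumor = roi_tumor$phase_means), 4)
print(wide)
cat(sprintf("\nFocus below whole lung at %d of %d post-baseline phases\n",
            sum(roi_tumor$phase_means[-1] < roi_lung$phase_means[-1]),
            vl$n_phases - 1L))
cat(sprintf("Early dip present: %s\n",
            any(diff(roi_tumor$phase_means[1:4]) < 0)))
cat("Curves written to results/roi_curves.csv\n")
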