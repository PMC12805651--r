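---
title: "Methods: regional ventilation metrics, lung mechanics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional ventilation metrics, lung mechanics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xvlung)
```

# What this package computes

`xvlung` analyzes functional lung imaging of the kind produced by X-ray
velocimetry (XV) in small animals: a 3D map of *specific ventilation* (SV)
— the fractional volume change of each lung voxel over a breath, relative
to its volume at peak exhalation — sampled at several phase points across
the breath, together with a paired CT volume and a lung mask. From these it
derives the global metrics used to characterize ventilation in murine
lung-tumor models, estimates the standard forced-maneuver lung-mechanics
battery from ventilator traces, and runs the cohort statistics that relate
both to tumor burden. A synthetic-cohort generator supplies ground-truthed
virtual mice so that the entire pipeline is verifiable end to end.

# Ventilation metrics

All metrics are computed over the lung mask only; voxels outside the mask
can never influence a result (this is enforced by tests that perturb
out-of-mask voxels).

**MSV** is the arithmetic mean of SV over masked voxels of the
peak-inspiration volume. Because each phase volume stores cumulative
expansion from phase 0 (peak exhalation), the final phase *is* the
exhalation-to-inspiration measurement that the scalar metrics refer to.

**Tidal volume** is the summed voxel expansion
$V_T = \sum_i \mathrm{SV}_i \cdot v_{\mathrm{vox}}$, converted from mm³ to
ml. This treats SV as fractional expansion of the resting voxel volume,
which makes $V_T$ exactly linear in the field.

**VDP and nVDP.** The ventilation defect percentage is the share of lung
voxels with SV below a threshold, conventionally 60% of a reference MSV:

$$\mathrm{VDP} = 100 \cdot
  \frac{\#\{i : \mathrm{SV}_i < f \cdot \mathrm{MSV}_{\mathrm{ref}}\}}
       {\#\{\text{masked voxels}\}}, \qquad f = 0.6 .$$

One function serves both variants: with the animal's own MSV as reference
it is VDP; with the mean MSV of the control population it is the
normalized variant nVDP, which can detect globally depressed ventilation
that a self-referenced threshold hides. The cohort generator computes the
control reference as the mean MSV over control animals; using another
summary (e.g. a pooled-voxel mean) is possible by passing `reference_msv`
directly.

**VH** is the interquartile range of masked SV divided by its mean — a
scale-free dispersion index. The IQR uses linearly interpolated quantiles
(`stats::quantile` type 7). The convention matters at small voxel counts,
so it is configurable and shared with the boxplot summaries, keeping the
two IQRs consistent.

## Spatial scale decomposition (VH~SS~, VH~LS~)

Heterogeneity is split into small-scale (intra-lobe) and large-scale
(inter-lobe) components by filtering the field before computing VH. The
low-pass filter is a separable Gaussian whose standard deviation is
`cutoff_mm` (default 2.0 mm — roughly the lobe scale of a mouse lung, the
boundary between "within a lobe" and "between lobes"); the high-pass
component is the exact residual, so the two components always sum back to
the original field on the mask.

The convolution is *masked and renormalized*: the field is multiplied by
the mask, both are convolved, and the ratio is taken on the mask. In-mask
averages therefore draw only on in-mask voxels; a bright artifact outside
the lung cannot bleed into the metrics.

$$\mathrm{VH}_{LS} = \frac{\mathrm{IQR}(\mathrm{low})}{\mathrm{mean}(\mathrm{low})},
\qquad
\mathrm{VH}_{SS} = \frac{\mathrm{IQR}(\mathrm{high})}{\mathrm{mean}(\mathrm{SV})} .$$

The high-pass component has near-zero mean by construction, so dividing
its IQR by its own mean would be numerically meaningless; the original
field's in-mask mean is used instead. This is a deliberate design choice,
recorded here because it departs from a literal "VH of the filtered
field".

## ROI phase curves

`extract_roi_curve()` returns the mean and SD of SV over the intersection
of an axis-aligned box with the lung mask, at every phase. Boxes are given
in mm as half-open intervals $[lo, hi)$ per axis; a voxel belongs to the
box if its center lies inside (0-based voxel indexing, voxel (0,0,0)
centered at the volume origin). With the whole-lung bounding box the
function reproduces the whole-lung curve exactly, which doubles as a test
oracle.

# Lung mechanics

The forced-maneuver battery mirrors standard small-animal ventilator
practice. The vendor software's internal model equations are not public;
the package uses the literature-standard forms throughout:

* **Single compartment** (snapshot maneuver): the equation of motion
  $P = R_{rs}\dot V + V/C_{rs} + P_0$, fitted by multiple linear
  regression of pressure on flow and volume. CoD is the regression $R^2$.
* **Constant phase** (forced oscillation): input impedance
  $Z(f) = R_n + i\,2\pi f I + (G - iH)/(2\pi f)^{\alpha}$ with
  $\alpha = \tfrac{2}{\pi}\arctan(H/G)$, fitted by Levenberg–Marquardt on
  stacked real and imaginary residuals. $G$ and $H$ are optimized on the
  log scale to keep them positive; starting values come from linearized
  fits of the real part (for $R_n, G$) and imaginary part (for $I, H$) at
  a provisional $\alpha = 0.7$. Iteration cap 200, relative tolerance
  1e-12. The default frequency grid is 13 log-spaced points over
  1–20.5 Hz, a typical mouse forced-oscillation range.
* **Pressure–volume deflation limb**: the Salazar–Knowles exponential
  $V = A - B e^{-KP}$, initialized from a log-linear fit. Static
  compliance is the slope at zero pressure, $C_{st} = BK$; a chord
  definition over a configurable pressure interval is available because
  vendor conventions differ. Loop area is the unsigned shoelace area of
  the closed loop.
* **NPFE**: FVC is the trapezoidal integral of expiratory flow; FEV~0.05~
  integrates to exactly 0.05 s with linear interpolation at the boundary;
  FEF~0.05~ is the interpolated instantaneous flow there. No
  body-temperature correction is applied.
* **Deep inflation**: IC is the maximum volume above the PEEP baseline.

**Replicate averaging and CoD gating.** Three replicates are measured per
animal; for each parameter, only replicates whose governing model fit has
a coefficient of determination of at least 0.9 enter the average (0.9
itself is retained; "below 0.9" is excluded). Parameters with every
replicate excluded are *missing*, never zero, and missingness propagates
to the statistics stage, which deletes pairwise. Parameters not produced
by a model fit (IC, the NPFE indices) are always averaged.

Noiseless self-generated data round-trip through every fit with relative
error below 1e-4 and CoD exactly 1 — this is a continuously tested
invariant, not an aspiration.

# The synthetic cohort

The generator's purpose is to reproduce the *statistical structure* the
analysis assumes, not biophysical fidelity: no airway tree, no
finite-element tissue, no projection physics.

* **Geometry**: two ellipsoidal lung fields (semi-axes ≈ 2.2 × 2.9 ×
  7.2 mm, ±3% seeded jitter) separated by a 2 mm midline gap on a
  32 × 20 × 40 grid at 0.4 mm isotropic spacing — about 5900 in-mask
  voxels, matching the ~6000-voxel scale of mouse XV maps.
* **Healthy dynamics**: voxel SV at phase $k$ is
  $\mathrm{SV}_0 \cdot p(k) \cdot \varepsilon_i$ with baseline
  $\mathrm{SV}_0 = 0.2$, concave inflation profile
  $p(k) \propto 1 - e^{-3k/(K-1)}$ (rapid early expansion, late plateau)
  over $K = 10$ phases, and fixed per-voxel lognormal noise
  $\varepsilon_i$ (unit mean, $\sigma_{\log} = 0.3$) shared across phases.
  Multiplicative lognormal noise keeps SV positive with occasional
  near-zero voxels, the empirically plausible shape for ventilation maps.
* **Tumor foci**: spheres with centers rejection-sampled inside the mask,
  radii uniform in 0.4–1.2 mm. Focus voxels get amplitude suppressed by
  `sv_suppression` and a delayed profile; with `fill_delay` active the
  focus barely expands at phase 1 and *contracts* at phase 2 (negative SV
  — local compression) before filling slowly, reproducing the early-dip,
  slow-filling trajectory seen in localized defects. Overlapping foci
  merge for burden accounting but are counted separately, mirroring
  histological focus counting. On CT, foci are bright (600 vs 200
  arbitrary units, Gaussian noise SD 15 — a synthetic convention, not
  calibrated HU).
* **Severity coupling**: a scalar severity in [0, 1] drives both imaging
  and mechanics. Foci count scales as `ceiling(50 * severity)` and
  suppression as `0.4 + 0.5 * severity`; mechanics scale as
  $(1 - \lambda s)$ for compliance-like parameters (C, recruitable PV
  volume, IC, NPFE peak flow) and $(1 + \lambda s)$ for R and H, with
  $\lambda = 0.5$. Severity 0 is the identity. Group severity ranges are
  control = 0, week-2 ∈ [0.05, 0.25], week-3 ∈ [0.55, 0.9] — ordered by
  construction, with mean burdens of roughly 5% and 20%. These are free
  parameters chosen once to give ordered, well-separated groups at the
  pilot's sample sizes (2/3/3).
* **Determinism**: all randomness flows from one cohort seed; per-animal
  and per-replicate seeds are derived arithmetically (modulo a prime below
  2^31), so a cohort regenerates byte-identically.

## What the phantom does and does not show

Passing tests demonstrate that the *pipeline* recovers planted structure:
lower MSV, higher nVDP, brighter CT, stiffer mechanics, and negative
compliance-vs-log10(count) correlations, in ≥ 90% of seeded cohorts.
They do not validate the metrics against real XV reconstructions, real
CT calibration, or real tissue mechanics. Two known divergences from
observed tumor-model behaviour:

* Real 3-week disease can *homogenize* ventilation globally (lower
  VH~LS~) as widespread stiffening depresses the whole map; the phantom's
  patchy foci instead *increase* VH~LS~ with burden. The phantom captures
  the localized-defect regime (the 2-week picture), not global
  homogenization.
* Tumor burden magnitudes are not calibrated to histology; only ordering
  and separation between groups are designed in.

# Statistics

Each parameter is analyzed with a one-way linear model on group
(`lm(y ~ group)`); estimated marginal means (which equal group sample
means in this design — verified to machine precision) and Tukey-adjusted
pairwise contrasts come from **emmeans**. The adjustment is configurable
(none/Bonferroni) and always reported in the output. Weight comparisons
use the Welch unequal-variance t-test. Correlations with tumor burden use
Pearson's r between the parameter and log10 tumor count, with p from the
t-transform on $n-2$ df; animals with zero counts are excluded by default
(log of zero), with a documented `log10(count + 1)` option that keeps
them. Missing cells (e.g. an excluded mechanics session) are deleted
pairwise per parameter. No correction is applied across parameters.

Degenerate inputs raise errors rather than returning sentinels: empty
masks, zero-mean fields for VH, all-constant samples in the t-test,
zero-variance correlations. One deliberate exception: with zero residual
variance in the group model, zero contrasts get p = 1 and nonzero ones
p = 0, so an all-identical table is reportable.

# Verification problem sizes

The shipped test-suite and acceptance script verify, at these sizes chosen
to keep a full run within a few minutes on one core: metric-vs-oracle
agreement on 1000 random ≤ 5³ fields (plus 25 for the convolution oracle),
filter complementarity on 100 phantoms, noiseless round trips plus 100
noisy replicates per mechanics model, CoD gating on 4 constructed replicate
triples, effect-direction recovery over 50 simulated cohorts of 8 animals,
and closed-form statistics agreement on fixed small vectors.
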