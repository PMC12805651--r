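Package: xvlung
Title: Regional Lung Ventilation Metrics, Forced-Oscillation Mechanics and
    Cohort Statistics for Murine Lung-Tumor Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of 3D specific-ventilation maps of the
    mouse lung and of ventilator-derived lung mechanics. Computes global
    ventilation metrics (mean specific ventilation, tidal volume,
    ventilation defect percentage against per-animal or control-population
    thresholds, ventilation heterogeneity and its small-/large-spatial-scale
    decomposition via masked Gaussian filtering, mean CT gray value) and
    phase-resolved region-of-interest expansion curves. Estimates the
    standard small-animal mechanics battery (single-compartment resistance
    and compliance, constant-phase model parameters, Salazar-Knowles
    pressure-volume fit, forced-expiration indices, inspiratory capacity)
    from pressure/flow/volume traces with replicate averaging gated on the
    coefficient of determination. A synthetic-cohort generator plants dense,
    poorly ventilated, slow-filling tumor foci in virtual lungs with
    burden-coupled mechanics, so the full pipeline - simulation, metrics,
    mechanics, group statistics and tumor-count correlations - runs end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    minpack.lm,
    emmeans,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
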