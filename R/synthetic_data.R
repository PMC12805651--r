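## Synthetic cohorts: virtual lungs with planted tumor foci that are denser
## on CT, less ventilated and slow-filling, plus burden-coupled mechanics.
## The generator provides ground truth (foci count, burden, true mechanics)
## so every downstream stage is testable without any acquired data.

#' Virtual-lung defaults
#'
#' Geometry, baseline ventilation and healthy mechanics of the simulated
#' mouse lung. The default grid at 0.4 mm isotropic spacing yields on the
#' order of 6000 in-mask voxels. The inflation profile is concave
#' (rapid early expansion, late plateau): `1 - exp(-3k/(K-1))`, normalized
#' to end at 1.
#'
#' @param shape grid dimensions.
#' @param spacing_mm voxel spacing (mm).
#' @param baseline_sv mean specific ventilation of healthy tissue at peak
#'   inspiration.
#' @param sv_noise_sdlog SD of the voxelwise multiplicative lognormal noise
#'   (log scale; the noise has unit mean).
#' @param n_phases breath-phase points per breath.
#' @param ct_lung_gray,ct_tumor_gray mean CT gray values (arbitrary scanner
#'   units; synthetic convention, not calibrated HU).
#' @param ct_noise_sd additive CT gray noise SD.
#' @param mech_params healthy-lung mechanics: list with `r`, `c`, `cp`
#'   (a [constant_phase_params()]), `pv_a`, `pv_b`, `pv_k`, `ic`,
#'   `npfe_q0`, `npfe_tau`.
#' @return List of class `virtual_lung`.
#' @export
virtual_lung <- function(shape = c(32L, 20L, 40L),
                         spacing_mm = c(0.4, 0.4, 0.4),
                         baseline_sv = 0.2,
                         sv_noise_sdlog = 0.3,
                         n_phases = 10L,
                         ct_lung_gray = 200,
                         ct_tumor_gray = 600,
                         ct_noise_sd = 15,
                         mech_params = list(
                           r = 0.5, c = 0.05,
                           cp = constant_phase_params(rn = 0.3,
                                                      i_inert = 0.005,
                                                      g = 4, h = 25),
                           pv_a = 0.9, pv_b = 0.6, pv_k = 0.1,
                           ic = 0.8, npfe_q0 = 30, npfe_tau = 0.04)) {
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 baseline_sv = baseline_sv, sv_noise_sdlog = sv_noise_sdlog,
                 n_phases = as.integer(n_phases),
                 ct_lung_gray = ct_lung_gray, ct_tumor_gray = ct_tumor_gray,
                 ct_noise_sd = ct_noise_sd, mech_params = mech_params),
            class = "virtual_lung")
}

#' Concave inflation profile
#'
#' Per-phase fraction of full expansion: starts at 0, ends at 1,
#' non-decreasing and concave, emulating rapid early inflation followed by
#' a plateau toward peak inspiration.
#'
#' @param n_phases number of phase points.
#' @param rate shape constant of the saturating exponential.
#' @return Numeric vector of length `n_phases` in `[0, 1]`.
#' @export
inflation_profile <- function(n_phases, rate = 3) {
  k <- seq(0, n_phases - 1)
  p <- 1 - exp(-rate * k / (n_phases - 1))
  p / p[n_phases]
}

# Delayed, initially dipping expansion profile for tumor foci. With a
# positive fill delay the focus barely expands at phase 1 and contracts at
# phase 2 (negative SV, local compression) before filling slowly.
tumor_profile <- function(n_phases, fill_delay = 1L, dip = 0.05, rate = 3) {
  k <- seq(0, n_phases - 1)
  ks <- pmax(k - fill_delay, 0)
  p <- 1 - exp(-rate * ks / (n_phases - 1))
  p <- p / max(1 - exp(-rate), 1e-12)
  if (fill_delay > 0 && n_phases >= 4) {
    p[2] <- dip
    p[3] <- -dip
    # keep the tail non-decreasing after the dip
    for (i in seq(4, n_phases)) p[i] <- max(p[i], p[i - 1])
  }
  p
}

#' Generate an ellipsoidal two-lobe lung mask
#'
#' Two ellipsoids (left/right lung fields) separated by a midline gap, with
#' small seeded jitter of the semi-axes. At the default shape and 0.4 mm
#' spacing the mask holds roughly 6000 voxels.
#'
#' @param shape grid dimensions (length 3).
#' @param spacing voxel spacing in mm.
#' @param seed integer seed (jitters the ellipsoid semi-axes).
#' @return A [lung_mask()].
#' @export
generate_lung_mask <- function(shape = c(32L, 20L, 40L),
                               spacing = c(0.4, 0.4, 0.4), seed = 1L) {
  if (any(shape < 8L)) stop("grid too small to contain the lung ellipsoids")
  set.seed(seed)
  semi <- c(2.2, 2.9, 7.2) * runif(3, 0.97, 1.03)   # mm
  gap <- 1.0                                         # midline half-gap, mm
  ctr <- (shape - 1) / 2 * spacing
  cx <- voxel_centers(shape[1], spacing[1], 0)
  cy <- voxel_centers(shape[2], spacing[2], 0)
  cz <- voxel_centers(shape[3], spacing[3], 0)
  dx_l <- (cx - (ctr[1] - gap - semi[1])) / semi[1]
  dx_r <- (cx - (ctr[1] + gap + semi[1])) / semi[1]
  dy <- (cy - ctr[2]) / semi[2]
  dz <- (cz - ctr[3]) / semi[3]
  d2y <- outer(dy^2, dz^2, "+")
  m <- array(FALSE, shape)
  for (i in seq_len(shape[1])) {
    m[i, , ] <- (dx_l[i]^2 + d2y < 1) | (dx_r[i]^2 + d2y < 1)
  }
  if ((semi[1] * 2 + gap) * 2 > shape[1] * spacing[1] ||
      semi[2] * 2 > shape[2] * spacing[2] || semi[3] * 2 > shape[3] * spacing[3])
    stop("grid too small to contain the lung ellipsoids")
  lung_mask(m)
}

#' Tumor foci specification
#'
#' @param n_foci number of spherical foci to plant.
#' @param radius_mm length-2 range of focus radii (uniform sampling).
#' @param sv_suppression multiplicative reduction of specific-ventilation
#'   amplitude inside foci, in `[0, 1]` (1 = no ventilation).
#' @param fill_delay phase lag (integer phases) producing slow filling and
#'   the early dip; 0 disables the dip.
#' @param severity scalar in `[0, 1]` coupling burden to mechanics shifts.
#' @param seed integer seed for focus placement.
#' @return List of class `tumor_foci_spec`.
#' @export
tumor_foci_spec <- function(n_foci = 0L, radius_mm = c(0.4, 1.2),
                            sv_suppression = 0.6, fill_delay = 1L,
                            severity = 0, seed = 1L) {
  if (sv_suppression < 0 || sv_suppression > 1)
    stop("sv_suppression must lie in [0, 1]")
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  structure(list(n_foci = as.integer(n_foci), radius_mm = radius_mm,
                 sv_suppression = sv_suppression,
                 fill_delay = as.integer(fill_delay),
                 severity = severity, seed = as.integer(seed)),
            class = "tumor_foci_spec")
}

#' Derive a foci specification from a severity score
#'
#' Maps the scalar severity in `[0, 1]` to a focus count and ventilation
#' suppression; severity 0 yields no foci.
#'
#' @param severity scalar in `[0, 1]`.
#' @param seed placement seed.
#' @export
foci_spec_from_severity <- function(severity, seed = 1L) {
  tumor_foci_spec(n_foci = ceiling(severity * 50),
                  radius_mm = c(0.4, 1.2),
                  sv_suppression = min(1, 0.4 + 0.5 * severity),
                  fill_delay = 1L, severity = severity, seed = seed)
}

#' Generate a phase-resolved phantom with planted tumor foci
#'
#' Healthy voxels expand along the concave inflation profile with fixed
#' voxelwise lognormal amplitude noise; focus voxels get a suppressed
#' amplitude and a delayed, initially dipping profile. The paired CT is
#' bright inside foci (denser tissue) and dim elsewhere. Overlapping foci
#' are merged for burden accounting but counted separately.
#'
#' @param vl a [virtual_lung()].
#' @param foci a [tumor_foci_spec()].
#' @param mask optional pre-built [lung_mask()]; generated from
#'   `foci$seed` when omitted.
#' @return List with `series` ([phase_series()]), `ct` ([ct_volume()]) and
#'   `truth` (list: `tumor_count`, `tumor_burden_pct`, `foci_centers_mm`,
#'   `foci_radii_mm`, `tumor_voxels` logical array, `severity`).
#' @export
generate_phase_series <- function(vl = virtual_lung(),
                                  foci = tumor_foci_spec(),
                                  mask = NULL) {
  if (is.null(mask)) mask <- generate_lung_mask(vl$shape, vl$spacing_mm,
                                                seed = foci$seed)
  shape <- dim(mask$values)
  set.seed(foci$seed + 7L)

  # plant spherical foci with in-mask rejection sampling of centers
  tumor <- array(FALSE, shape)
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  if (foci$n_foci > 0) {
    in_idx <- which(mask$values, arr.ind = TRUE)
    cx <- voxel_centers(shape[1], vl$spacing_mm[1], 0)
    cy <- voxel_centers(shape[2], vl$spacing_mm[2], 0)
    cz <- voxel_centers(shape[3], vl$spacing_mm[3], 0)
    pick <- sample(nrow(in_idx), foci$n_foci, replace = TRUE)
    for (j in seq_len(foci$n_foci)) {
      ijk <- in_idx[pick[j], ]
      ctr <- c(cx[ijk[1]], cy[ijk[2]], cz[ijk[3]])
      r <- runif(1, foci$radius_mm[1], foci$radius_mm[2])
      lo <- pmax(1L, floor((ctr - r) / vl$spacing_mm) + 1L)
      hi <- pmin(shape, ceiling((ctr + r) / vl$spacing_mm) + 1L)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      for (ix in xs) for (iy in ys) {
        dz2 <- (cz[zs] - ctr[3])^2
        d2 <- (cx[ix] - ctr[1])^2 + (cy[iy] - ctr[2])^2 + dz2
        tumor[ix, iy, zs] <- tumor[ix, iy, zs] | (d2 <= r^2)
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
    tumor <- tumor & mask$values
    if (sum(tumor) >= mask$n_voxels)
      stop("requested foci volume exceeds the lung mask")
  }

  # fixed voxelwise amplitude noise (unit-mean lognormal), shared by phases
  noise <- array(1, shape)
  nin <- mask$n_voxels
  noise[mask$values] <- rlnorm(nin, meanlog = -vl$sv_noise_sdlog^2 / 2,
                               sdlog = vl$sv_noise_sdlog)

  prof_h <- inflation_profile(vl$n_phases)
  prof_t <- tumor_profile(vl$n_phases, foci$fill_delay)
  amp_t <- 1 - foci$sv_suppression

  vols <- vector("list", vl$n_phases)
  base <- array(0, shape)
  healthy <- mask$values & !tumor
  for (k in seq_len(vl$n_phases)) {
    v <- base
    v[healthy] <- vl$baseline_sv * prof_h[k] * noise[healthy]
    if (any(tumor))
      v[tumor] <- vl$baseline_sv * amp_t * prof_t[k] * noise[tumor]
    vols[[k]] <- ventilation_volume(v, vl$spacing_mm, phase_index = k - 1L)
  }
  series <- phase_series(vols, mask)

  ct <- array(0, shape)
  ct[mask$values] <- vl$ct_lung_gray
  ct[tumor] <- vl$ct_tumor_gray
  ct[mask$values] <- ct[mask$values] +
    rnorm(nin, sd = vl$ct_noise_sd)
  ct <- ct_volume(ct, vl$spacing_mm)

  truth <- list(
    tumor_count = nrow(centers),
    tumor_burden_pct = 100 * sum(tumor) / mask$n_voxels,
    foci_centers_mm = centers,
    foci_radii_mm = radii,
    tumor_voxels = tumor,
    severity = foci$severity
  )
  list(series = series, ct = ct, truth = truth)
}

#' Couple mechanics parameters to tumor burden
#'
#' Tumor growth stiffens and shrinks the functional lung: compliance-like
#' parameters (C, C_st via the recruitable PV volume, IC, FVC via the NPFE
#' peak flow) scale by `(1 - lambda*severity)`, while resistance R and
#' tissue elastance H scale by `(1 + lambda*severity)`. Severity 0 is the
#' identity.
#'
#' @param base_params healthy mechanics list (see [virtual_lung()]).
#' @param severity scalar in `[0, 1]`.
#' @param lambda coupling strength (default 0.5).
#' @return Mechanics parameter list of the same shape.
#' @export
couple_mechanics_to_burden <- function(base_params, severity, lambda = 0.5) {
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]")
  dn <- 1 - lambda * severity
  up <- 1 + lambda * severity
  p <- base_params
  p$c <- p$c * dn
  p$pv_a <- p$pv_a * dn
  p$pv_b <- p$pv_b * dn          # C_st = B*K scales with B
  p$ic <- p$ic * dn
  p$npfe_q0 <- p$npfe_q0 * dn    # FVC = Q0*tau scales with Q0
  p$r <- p$r * up
  p$cp <- constant_phase_params(p$cp$rn, p$cp$i_inert, p$cp$g, p$cp$h * up)
  p
}

#' Cohort configuration
#'
#' Defaults mirror the pilot design: 2 control, 3 two-week and 3 three-week
#' animals, with severity increasing by group.
#'
#' @param group_sizes named integer vector (control, week2, week3).
#' @param severity_ranges list of length-2 severity ranges per group.
#' @param n_phases breath phases per series.
#' @param mark_leak if `TRUE`, one animal's mechanics are dropped (set
#'   missing), emulating an unusable mechanics session.
#' @export
cohort_config <- function(group_sizes = c(control = 2L, week2 = 3L,
                                          week3 = 3L),
                          severity_ranges = list(control = c(0, 0),
                                                 week2 = c(0.05, 0.25),
                                                 week3 = c(0.55, 0.9)),
                          n_phases = 10L, mark_leak = FALSE) {
  if (any(group_sizes < 1L)) stop("every group needs at least one animal")
  list(group_sizes = group_sizes, severity_ranges = severity_ranges,
       n_phases = as.integer(n_phases), mark_leak = mark_leak)
}

# Deterministic per-animal seed from the cohort seed (kept below 2^31).
animal_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483587)
}

#' Simulate a complete cohort in memory
#'
#' For each animal: a seeded lung mask, a phase series with severity-derived
#' tumor foci, a paired CT, and a full mechanics session with
#' burden-coupled parameters. XV metrics are computed per animal; nVDP is
#' referenced to the mean MSV of the control group.
#'
#' @param config a [cohort_config()].
#' @param seed master cohort seed; all per-animal seeds derive from it.
#' @param vl a [virtual_lung()] (its `n_phases` is overridden by `config`).
#' @param threshold_fraction,cutoff_mm metric settings.
#' @param keep_volumes keep per-animal volumes/traces in the result (needed
#'   by [generate_cohort()] for writing to disk).
#' @return List with `study_table` (one row per animal), `truth`
#'   (data.frame of ground truth) and, if requested, `animals`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            vl = virtual_lung(),
                            threshold_fraction = 0.6, cutoff_mm = 2.0,
                            keep_volumes = FALSE) {
  vl$n_phases <- config$n_phases
  set.seed(seed)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  sev <- numeric(n)
  for (g in names(config$group_sizes)) {
    idx <- which(groups == g)
    rng <- config$severity_ranges[[g]]
    sev[idx] <- runif(length(idx), rng[1], rng[2])
  }
  prefix <- c(control = "A", week2 = "B", week3 = "C")
  ids <- paste0(prefix[groups], stats::ave(seq_len(n), groups,
                                           FUN = seq_along))
  weight <- rnorm(n, mean = 20, sd = 1.2)

  animals <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- animal_seed(seed, i)
    foci <- foci_spec_from_severity(sev[i], seed = si)
    ph <- generate_phase_series(vl, foci)
    mech_true <- couple_mechanics_to_burden(vl$mech_params, sev[i])
    sess <- simulate_mechanics_session(mech_true, seed = si)
    rows[[i]] <- cbind(
      data.frame(animal_id = ids[i], group = groups[i], weight_g = weight[i],
                 severity = sev[i], tumor_count = ph$truth$tumor_count,
                 tumor_burden_pct = ph$truth$tumor_burden_pct),
      compute_xv_metrics(ph$series, ph$ct,
                         threshold_fraction = threshold_fraction,
                         cutoff_mm = cutoff_mm),
      sess$record)
    animals[[i]] <- list(id = ids[i], group = groups[i], severity = sev[i],
                         phantom = if (keep_volumes) ph else NULL,
                         truth = ph$truth[c("tumor_count", "tumor_burden_pct",
                                            "foci_centers_mm",
                                            "foci_radii_mm", "severity")],
                         mech_true = mech_true,
                         session = if (keep_volumes) sess else NULL)
  }
  tab <- do.call(rbind, rows)

  # nVDP referenced to the control-population mean MSV
  ref <- mean(tab$msv[tab$group == "control"])
  tab$reference_msv <- ref
  for (i in seq_len(n)) {
    ph <- if (keep_volumes) animals[[i]]$phantom else NULL
    if (is.null(ph)) {
      foci <- foci_spec_from_severity(sev[i], seed = animal_seed(seed, i))
      ph <- generate_phase_series(vl, foci)
    }
    tab$nvdp_pct[i] <- compute_vdp(ph$series, threshold_fraction = threshold_fraction,
                                   reference_msv = ref)
    if (keep_volumes) animals[[i]]$phantom <- ph
  }

  if (config$mark_leak) {
    # emulate one unusable 3-week mechanics session
    leak <- which(tab$group == "week3")[1]
    mech_cols <- c(.mech_params, paste0("n_", unique(.param_fit_map)))
    tab[leak, intersect(mech_cols, names(tab))] <- NA
  }

  truth <- tab[, c("animal_id", "group", "severity", "tumor_count",
                   "tumor_burden_pct")]
  list(study_table = tab, truth = truth,
       animals = if (keep_volumes) animals else NULL)
}

#' Generate a cohort and write all artifacts to disk
#'
#' Writes, per animal, the NIfTI phase series and mask, the paired CT,
#' representative maneuver CSVs and a `truth.json`; plus a cohort-level
#' `manifest.json`, `ground_truth.csv` and `study_table.csv`.
#'
#' @inheritParams simulate_cohort
#' @param out_dir output directory root.
#' @return The [simulate_cohort()] result, invisibly.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            out_dir, vl = virtual_lung(),
                            threshold_fraction = 0.6, cutoff_mm = 2.0) {
  res <- simulate_cohort(config, seed, vl, threshold_fraction, cutoff_mm,
                         keep_volumes = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (an in res$animals) {
    adir <- file.path(out_dir, an$id)
    write_phase_series(an$phantom$series, adir)
    write_ct_volume(an$phantom$ct, file.path(adir, "ct.nii.gz"))
    tdir <- file.path(adir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    tr <- simulate_single_compartment(an$mech_true$r, an$mech_true$c,
                                      seed = animal_seed(seed, 1L))
    write_trace_csv(tr, file.path(tdir, "snapshot.csv"))
    spec <- constant_phase_impedance(an$mech_true$cp, quickprime_frequencies())
    write.csv(spec, file.path(tdir, "quickprime_spectrum.csv"),
              row.names = FALSE)
    pv <- simulate_pv_maneuver(an$mech_true$pv_a, an$mech_true$pv_b,
                               an$mech_true$pv_k)
    write.csv(pv$loop, file.path(tdir, "pv_loop.csv"), row.names = FALSE)
    truth <- an$truth
    truth$foci_centers_mm <- unname(split(truth$foci_centers_mm,
                                          seq_len(max(1, nrow(truth$foci_centers_mm)))))
    if (an$truth$tumor_count == 0) truth$foci_centers_mm <- list()
    jsonlite::write_json(truth, file.path(adir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(res$truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(res$study_table, file.path(out_dir, "study_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, animals = vapply(res$animals, `[[`, "", "id"),
         groups = vapply(res$animals, `[[`, "", "group"),
         n_phases = config$n_phases),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
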