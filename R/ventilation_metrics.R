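## Global XV metrics over a lung mask, and the phase-resolved ROI analysis.
## All metrics are computed over masked voxels only; out-of-mask voxels can
## never influence a result.

#' Mean specific ventilation (MSV)
#'
#' Arithmetic mean of specific ventilation over the lung mask. When a
#' [phase_series()] is given the peak-inspiration (final-phase) volume is
#' used, since scalar XV metrics refer to expansion between peak exhalation
#' and peak inspiration.
#'
#' @param x a [ventilation_volume()], 3D array, or [phase_series()].
#' @param mask a [lung_mask()] (taken from the series if omitted).
#' @return Unitless mean specific ventilation.
#' @export
compute_msv <- function(x, mask = NULL) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  mean(vals[mask$values])
}

#' Tidal volume from a specific-ventilation map
#'
#' Summed voxel expansion: `V_T = sum(SV_i) * voxel_volume`, converted from
#' mm^3 to ml.
#'
#' @inheritParams compute_msv
#' @param spacing voxel spacing in mm; taken from `x` when it carries one.
#' @return Tidal volume in ml.
#' @export
compute_tidal_volume <- function(x, mask = NULL, spacing = NULL) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  if (is.null(spacing)) {
    if (!inherits(x, "ventilation_volume"))
      stop("spacing must be supplied for a bare array")
    spacing <- x$spacing
  }
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  sum(vals[mask$values]) * prod(spacing) / 1000
}

#' Ventilation defect percentage (VDP / nVDP)
#'
#' Percentage of lung voxels whose specific ventilation falls below
#' `threshold_fraction` of a reference MSV. With the default
#' `reference_msv = NULL` the volume's own MSV is used (VDP); supplying the
#' mean MSV of a control population gives the normalized variant (nVDP).
#' The conventional threshold fraction is 0.6.
#'
#' @inheritParams compute_msv
#' @param threshold_fraction fraction of the reference MSV defining a
#'   defect, in (0, 1); default 0.6.
#' @param reference_msv reference MSV; `NULL` for the volume's own MSV.
#' @return Percentage in `[0, 100]`.
#' @export
compute_vdp <- function(x, mask = NULL, threshold_fraction = 0.6,
                        reference_msv = NULL) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  sv <- vals[mask$values]
  if (is.null(reference_msv)) reference_msv <- mean(sv)
  if (!is.finite(reference_msv) || reference_msv <= 0)
    stop("non-positive reference MSV")
  100 * sum(sv < threshold_fraction * reference_msv) / mask$n_voxels
}

#' Ventilation heterogeneity (VH)
#'
#' Interquartile range of masked specific ventilation divided by its mean.
#' Scale-free: multiplying the field by a positive constant leaves VH
#' unchanged. The IQR uses linearly interpolated quantiles
#' (`stats::quantile` type 7) by default; the convention is configurable
#' because VH depends on it at small voxel counts.
#'
#' @inheritParams compute_msv
#' @param quantile_type passed to [stats::quantile()].
#' @return Unitless heterogeneity index (>= 0 for positive-mean fields).
#' @export
compute_vh <- function(x, mask = NULL, quantile_type = 7) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  sv <- vals[mask$values]
  m <- mean(sv)
  if (m == 0) stop("undefined VH for zero-mean field")
  q <- quantile(sv, c(0.25, 0.75), type = quantile_type, names = FALSE)
  (q[2] - q[1]) / m
}

# Shift a 3D array by k voxels along one axis, filling with zeros.
shift3 <- function(a, k, axis) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k > 0) seq.int(1 + k, n) else seq_len(n + k)
  idx_src <- lapply(seq_len(3), function(ax) if (ax == axis) src else seq_len(d[ax]))
  idx_dst <- lapply(seq_len(3), function(ax) if (ax == axis) dst else seq_len(d[ax]))
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Separable Gaussian convolution of a zero-filled 3D field; sigma in voxels
# per axis; kernel truncated at 4 sigma.
gauss_conv3 <- function(a, sigma_vox) {
  for (axis in seq_len(3)) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (j in seq_along(w)) {
      k <- j - r - 1L
      acc <- acc + w[j] * shift3(a, k, axis)
    }
    a <- acc
  }
  a
}

#' Spatial scale decomposition of a masked field
#'
#' Splits the in-mask field into a smooth large-scale (low-pass) component
#' and a fine-texture (high-pass) residual, using masked (renormalized)
#' Gaussian convolution so that out-of-mask voxels never contribute to
#' in-mask averages. The two components sum exactly to the original on the
#' mask (`high = original - low` by construction).
#'
#' @inheritParams compute_msv
#' @param cutoff_mm standard deviation of the Gaussian low-pass kernel in
#'   mm; default 2.0 mm, approximately the lobe scale, separating
#'   intra-lobe from inter-lobe variation. Must be at least one voxel.
#' @return List with 3D arrays `low_pass` and `high_pass` (zero outside the
#'   mask) and the logical `mask` used.
#' @export
decompose_scales <- function(x, mask = NULL, cutoff_mm = 2.0) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  spacing <- if (inherits(x, "ventilation_volume")) x$spacing else c(0.4, 0.4, 0.4)
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  if (cutoff_mm <= 0) stop("cutoff_mm must be > 0")
  if (cutoff_mm < max(spacing))
    stop("cutoff_mm must be at least one voxel on every axis")
  m <- array(as.numeric(mask$values), dim(vals))
  num <- gauss_conv3(vals * m, cutoff_mm / spacing)
  den <- gauss_conv3(m, cutoff_mm / spacing)
  low <- array(0, dim(vals))
  low[mask$values] <- num[mask$values] / den[mask$values]
  high <- array(0, dim(vals))
  high[mask$values] <- vals[mask$values] - low[mask$values]
  list(low_pass = low, high_pass = high, mask = mask$values)
}

#' Small- and large-scale ventilation heterogeneity (VH_SS, VH_LS)
#'
#' VH computed after spatial filtering: `vh_ls` is the VH of the low-pass
#' component; `vh_ss` is the IQR of the high-pass component divided by the
#' original field's in-mask mean (the high-pass component has near-zero
#' mean, so its own mean cannot normalize it).
#'
#' @inheritParams decompose_scales
#' @param quantile_type passed to [stats::quantile()].
#' @return Named numeric vector `c(vh_ss = , vh_ls = )`.
#' @export
compute_vh_scales <- function(x, mask = NULL, cutoff_mm = 2.0,
                              quantile_type = 7) {
  if (inherits(x, "phase_series")) {
    if (is.null(mask)) mask <- x$mask
    x <- peak_inspiration_volume(x)
  }
  vals <- vol_values(x)
  mask <- check_mask_compat(vals, mask)
  dec <- decompose_scales(x, mask, cutoff_mm)
  m <- mean(vals[mask$values])
  if (m == 0) stop("undefined VH for zero-mean field")
  q_hi <- quantile(dec$high_pass[mask$values], c(0.25, 0.75),
                   type = quantile_type, names = FALSE)
  vh_ss <- (q_hi[2] - q_hi[1]) / m
  q_lo <- quantile(dec$low_pass[mask$values], c(0.25, 0.75),
                   type = quantile_type, names = FALSE)
  vh_ls <- (q_lo[2] - q_lo[1]) / mean(dec$low_pass[mask$values])
  c(vh_ss = vh_ss, vh_ls = vh_ls)
}

#' Mean CT gray value over the lung
#'
#' @param ct a [ct_volume()] or 3D array of gray values.
#' @param mask a [lung_mask()].
#' @return Mean gray value in scanner units.
#' @export
mean_ct_gray <- function(ct, mask) {
  vals <- vol_values(ct)
  mask <- check_mask_compat(vals, mask)
  mean(vals[mask$values])
}

# Voxel-center coordinates (mm) along one axis, 0-based indexing.
voxel_centers <- function(n, spacing, origin) origin + (seq_len(n) - 1L) * spacing

#' Phase-resolved ROI expansion curve
#'
#' Mean and standard deviation of specific ventilation over the voxels in
#' an axis-aligned box intersected with the lung mask, at every phase
#' point. ROI bounds are in mm as half-open intervals `[lo, hi)` per axis;
#' a voxel belongs to the ROI if its center lies inside. Using the
#' whole-lung bounding box reproduces the whole-lung curve.
#'
#' @param series a [phase_series()].
#' @param roi_bounds_mm numeric length-6: `c(x0, x1, y0, y1, z0, z1)` mm.
#' @param label free-text label stored with the curve.
#' @return Object of class `roi_curve`: list with `phase_indices`,
#'   `phase_means`, `phase_sds`, `n_voxels`, `roi_bounds`, `label`.
#' @export
extract_roi_curve <- function(series, roi_bounds_mm, label = "") {
  stopifnot(inherits(series, "phase_series"))
  if (length(roi_bounds_mm) != 6L)
    stop("roi_bounds_mm must be c(x0, x1, y0, y1, z0, z1)")
  v0 <- series$volumes[[1]]
  d <- dim(v0$values)
  sel <- vector("list", 3)
  for (ax in seq_len(3)) {
    ctr <- voxel_centers(d[ax], v0$spacing[ax], v0$origin[ax])
    lo <- roi_bounds_mm[2 * ax - 1]; hi <- roi_bounds_mm[2 * ax]
    sel[[ax]] <- ctr >= lo & ctr < hi
  }
  roi <- array(FALSE, d)
  roi[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  roi <- roi & series$mask$values
  if (!any(roi)) stop("ROI does not intersect the lung mask")
  means <- sds <- numeric(series$n_phases)
  for (i in seq_len(series$n_phases)) {
    sv <- series$volumes[[i]]$values[roi]
    means[i] <- mean(sv)
    sds[i] <- if (length(sv) > 1L) sd(sv) else 0
  }
  structure(
    list(phase_indices = vapply(series$volumes, function(v) v$phase_index,
                                integer(1)),
         phase_means = means, phase_sds = sds, n_voxels = sum(roi),
         roi_bounds = as.numeric(roi_bounds_mm), label = label),
    class = "roi_curve"
  )
}

#' Bounding box of the lung mask in mm
#'
#' Half-open box guaranteed to contain every in-mask voxel center; feeding
#' it to [extract_roi_curve()] yields the whole-lung curve.
#'
#' @param series a [phase_series()].
#' @return Numeric length-6 `c(x0, x1, y0, y1, z0, z1)` in mm.
#' @export
whole_lung_bounds <- function(series) {
  v0 <- series$volumes[[1]]
  idx <- which(series$mask$values, arr.ind = TRUE)
  out <- numeric(6)
  for (ax in seq_len(3)) {
    ctr <- voxel_centers(dim(v0$values)[ax], v0$spacing[ax], v0$origin[ax])
    rng <- range(ctr[range(idx[, ax])])
    out[2 * ax - 1] <- rng[1] - v0$spacing[ax] / 2
    out[2 * ax] <- rng[2] + v0$spacing[ax] / 2
  }
  out
}

#' All global XV metrics for one animal
#'
#' Computes MSV, tidal volume, VDP, nVDP, VH, VH_SS, VH_LS and mean CT gray
#' from a phase series and its paired CT.
#'
#' @param series a [phase_series()].
#' @param ct a [ct_volume()] (or `NULL` to skip `mean_ct_gray`).
#' @param threshold_fraction defect threshold as a fraction of the
#'   reference MSV (default 0.6).
#' @param reference_msv control-population MSV for nVDP; `NULL` makes
#'   nVDP equal VDP (own reference).
#' @param cutoff_mm Gaussian scale cutoff for the VH decomposition.
#' @return One-row data.frame with columns msv, vt_ml, vdp_pct, nvdp_pct,
#'   vh, vh_ss, vh_ls, mean_ct_gray, threshold_fraction, reference_msv,
#'   cutoff_mm.
#' @export
compute_xv_metrics <- function(series, ct = NULL, threshold_fraction = 0.6,
                               reference_msv = NULL, cutoff_mm = 2.0) {
  stopifnot(inherits(series, "phase_series"))
  vol <- peak_inspiration_volume(series)
  mask <- series$mask
  msv <- compute_msv(vol, mask)
  vhs <- compute_vh_scales(vol, mask, cutoff_mm)
  data.frame(
    msv = msv,
    vt_ml = compute_tidal_volume(vol, mask),
    vdp_pct = compute_vdp(vol, mask, threshold_fraction),
    nvdp_pct = compute_vdp(vol, mask, threshold_fraction,
                           reference_msv = if (is.null(reference_msv)) msv
                                           else reference_msv),
    vh = compute_vh(vol, mask),
    vh_ss = vhs[["vh_ss"]],
    vh_ls = vhs[["vh_ls"]],
    mean_ct_gray = if (is.null(ct)) NA_real_ else mean_ct_gray(ct, mask),
    threshold_fraction = threshold_fraction,
    reference_msv = if (is.null(reference_msv)) msv else reference_msv,
    cutoff_mm = cutoff_mm
  )
}
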