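#' @importFrom stats quantile sd lm coef rnorm runif rlnorm median approx
#'   ave confint cor.test df.residual t.test
#' @importFrom utils read.csv write.csv head combn packageVersion
NULL

#' Specific-ventilation volume
#'
#' A 3D grid of specific ventilation (SV), the fractional expansion of each
#' voxel relative to its volume at the start of the breath (unitless).
#' Values may be negative (local compression) but must be finite.
#'
#' @param values 3D numeric array of specific ventilation.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of voxel (1,1,1) in mm.
#' @param phase_index integer breath-phase label (0 = peak exhalation).
#' @return An object of class `ventilation_volume`.
#' @export
ventilation_volume <- function(values, spacing = c(0.4, 0.4, 0.4),
                               origin = c(0, 0, 0), phase_index = 0L) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(dim(values) < 1L))
    stop("grid dimensions must be >= 1 on every axis")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must all be > 0")
  if (any(!is.finite(values)))
    stop("specific ventilation values must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), phase_index = as.integer(phase_index)),
    class = "ventilation_volume"
  )
}

#' Lung mask
#'
#' Boolean segmentation of the lung over which all global metrics are taken.
#'
#' @param values 3D logical (or coercible) array; `TRUE` marks lung voxels.
#' @return An object of class `lung_mask` with an `n_voxels` field.
#' @export
lung_mask <- function(values) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(values) <- "logical"
  if (any(is.na(values)))
    stop("mask must not contain NA")
  structure(
    list(values = values, n_voxels = sum(values)),
    class = "lung_mask"
  )
}

#' CT volume
#'
#' @param values 3D numeric array of gray values (scanner units).
#' @param spacing voxel edge lengths in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = c(0.4, 0.4, 0.4)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "ct_volume")
}

#' Phase-resolved series of specific-ventilation volumes
#'
#' One volume per breath-phase point, all relative to phase 0 (peak
#' exhalation), i.e. cumulative expansion, sharing a single lung mask.
#'
#' @param volumes list of [ventilation_volume()] with strictly increasing
#'   `phase_index` and identical shape and spacing.
#' @param mask a [lung_mask()] on the same grid.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(volumes, mask) {
  if (!length(volumes)) stop("phase series needs at least one volume")
  if (!inherits(mask, "lung_mask")) mask <- lung_mask(mask)
  shp <- dim(volumes[[1]]$values)
  sp <- volumes[[1]]$spacing
  idx <- vapply(volumes, function(v) v$phase_index, integer(1))
  for (v in volumes) {
    if (!inherits(v, "ventilation_volume"))
      stop("all elements must be ventilation_volume objects")
    if (!identical(dim(v$values), shp))
      stop("all volumes must share the same shape")
    if (max(abs(v$spacing - sp)) > 1e-9)
      stop("all volumes must share the same spacing")
  }
  if (any(diff(idx) <= 0))
    stop("phase_index must be strictly increasing")
  if (!identical(dim(mask$values), shp))
    stop("mask shape must match volume shape")
  structure(
    list(volumes = volumes, mask = mask, n_phases = length(volumes)),
    class = "phase_series"
  )
}

check_mask_compat <- function(values, mask) {
  if (!inherits(mask, "lung_mask")) mask <- lung_mask(mask)
  if (!identical(dim(values), dim(mask$values)))
    stop("shape mismatch between volume and mask")
  if (mask$n_voxels < 1L)
    stop("empty lung mask")
  mask
}

# Pull the 3D array out of a volume-like argument.
vol_values <- function(x) {
  if (inherits(x, c("ventilation_volume", "ct_volume"))) x$values else as.array(x)
}

#' Final-phase volume of a series
#'
#' Scalar XV metrics use specific ventilation measured between peak
#' exhalation and peak inspiration, i.e. the last phase volume (which is
#' cumulative expansion from phase 0).
#'
#' @param series a [phase_series()].
#' @return The final [ventilation_volume()].
#' @export
peak_inspiration_volume <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  series$volumes[[series$n_phases]]
}

## ---- NIfTI I/O ------------------------------------------------------------

#' Write a phase series to per-phase NIfTI files with a JSON manifest
#'
#' @param series a [phase_series()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_phase_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(series$n_phases)
  for (i in seq_len(series$n_phases)) {
    v <- series$volumes[[i]]
    f <- sprintf("phase_%02d.nii.gz", v$phase_index)
    img <- RNifti::asNifti(v$values, pixdim = v$spacing)
    RNifti::writeNifti(img, file.path(dir, f))
    files[i] <- f
  }
  mask_file <- "mask.nii.gz"
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(series$mask$values),
                          dim(series$mask$values)),
                    pixdim = series$volumes[[1]]$spacing),
    file.path(dir, mask_file))
  manifest <- list(
    phase_files = files,
    phase_indices = vapply(series$volumes, function(v) v$phase_index, integer(1)),
    mask_file = mask_file,
    spacing_mm = series$volumes[[1]]$spacing,
    origin_mm = series$volumes[[1]]$origin
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a phase series written by [write_phase_series()]
#'
#' @param dir directory containing `manifest.json` and the NIfTI files.
#' @return A [phase_series()].
#' @export
read_phase_series <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spacing <- as.numeric(manifest$spacing_mm)
  origin <- as.numeric(manifest$origin_mm)
  vols <- lapply(seq_along(manifest$phase_files), function(i) {
    img <- RNifti::readNifti(file.path(dir, manifest$phase_files[i]))
    ventilation_volume(array(as.numeric(img), dim(img)), spacing, origin,
                       manifest$phase_indices[i])
  })
  mimg <- RNifti::readNifti(file.path(dir, manifest$mask_file))
  mask <- lung_mask(array(as.numeric(mimg) > 0.5, dim(mimg)))
  phase_series(vols, mask)
}

#' Write a CT volume as NIfTI
#' @param ct a [ct_volume()].
#' @param path output file path (.nii or .nii.gz).
#' @export
write_ct_volume <- function(ct, path) {
  RNifti::writeNifti(RNifti::asNifti(ct$values, pixdim = ct$spacing), path)
  invisible(path)
}

#' Read a CT volume from NIfTI
#' @param path NIfTI file path.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)),
            spacing = RNifti::pixdim(img)[seq_len(3)])
}
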