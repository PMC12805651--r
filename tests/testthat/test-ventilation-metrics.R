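test_that("MSV is the masked arithmetic mean", {
  m <- array(TRUE, c(10, 10, 10))
  v <- array(0.15, c(10, 10, 10))
  expect_equal(compute_msv(v, m), 0.15)

  v5 <- array(0, c(5, 1, 1)); v5[, 1, 1] <- c(0.1, 0.2, 0.2, 0.2, 0.3)
  expect_equal(compute_msv(v5, array(TRUE, c(5, 1, 1))), 0.2)

  # out-of-mask voxels are excluded entirely
  m2 <- array(c(TRUE, FALSE), c(4, 2, 2))
  v2 <- array(9.9, c(4, 2, 2)); v2[m2] <- 0.1
  expect_equal(compute_msv(v2, m2), 0.1)
})

test_that("tidal volume sums voxel expansion and converts to ml", {
  d <- c(10, 10, 1)
  m <- array(FALSE, d); m[1:10, 1:10, 1] <- TRUE   # 100 voxels
  v <- ventilation_volume(array(0.1, d), spacing = c(0.4, 0.4, 0.4))
  expect_equal(compute_tidal_volume(v, m), 100 * 0.1 * 0.064 / 1000)
  expect_equal(compute_tidal_volume(ventilation_volume(2 * v$values), m),
               2 * compute_tidal_volume(v, m))
  expect_equal(compute_tidal_volume(ventilation_volume(0 * v$values), m), 0)
})

test_that("VDP counts voxels below the threshold fraction of the reference", {
  d <- c(5, 1, 1)
  m <- array(TRUE, d)
  v <- array(c(0.1, 0.2, 0.2, 0.2, 0.3), d)
  # own MSV 0.2, threshold 0.12: exactly one voxel below
  expect_equal(compute_vdp(v, m, threshold_fraction = 0.6), 20)
  # uniform field never falls below a strict fraction of its own mean
  expect_equal(compute_vdp(array(0.2, d), m, 0.6), 0)
  # monotone in threshold fraction and in the reference MSV
  expect_true(compute_vdp(v, m, 0.9) >= compute_vdp(v, m, 0.6))
  expect_true(compute_vdp(v, m, 0.6, reference_msv = 0.5) >=
                compute_vdp(v, m, 0.6, reference_msv = 0.2))
  expect_error(compute_vdp(v, m, 0.6, reference_msv = -1), "reference MSV")
  expect_error(compute_vdp(v, m, 1.2), "threshold_fraction")
})

test_that("VH is IQR over mean with interpolated quantiles, scale-free", {
  d <- c(5, 1, 1)
  m <- array(TRUE, d)
  v <- array(1:5, d)
  expect_equal(compute_vh(v, m), 2 / 3)
  expect_equal(compute_vh(array(0.3, d), m), 0)
  expect_equal(compute_vh(10 * v, m), compute_vh(v, m))
  expect_error(compute_vh(array(0, d), m), "zero-mean")
})

test_that("vectorized metrics match brute-force per-voxel oracles", {
  for (s in 1:200) {
    cs <- random_small_case(s)
    expect_equal(compute_msv(cs$values, cs$mask),
                 oracle_msv(cs$values, cs$mask), tolerance = 1e-12)
    expect_equal(compute_tidal_volume(cs$values, cs$mask, spacing = c(0.4, 0.4, 0.4)),
                 oracle_vt_ml(cs$values, cs$mask, c(0.4, 0.4, 0.4)),
                 tolerance = 1e-12)
    ref <- oracle_msv(cs$values, cs$mask)
    expect_equal(compute_vdp(cs$values, cs$mask, 0.6),
                 oracle_vdp(cs$values, cs$mask, 0.6, ref), tolerance = 1e-12)
    expect_equal(compute_vh(cs$values, cs$mask),
                 oracle_vh(cs$values, cs$mask), tolerance = 1e-12)
    expect_equal(mean_ct_gray(cs$values, cs$mask),
                 oracle_msv(cs$values, cs$mask), tolerance = 1e-12)
  }
})

test_that("scale decomposition is complementary and mask-respecting", {
  set.seed(11)
  d <- c(8, 8, 8)
  m <- array(runif(prod(d)) < 0.8, d); m[1, 1, 1] <- TRUE
  v <- ventilation_volume(array(runif(prod(d), 0, 0.4), d),
                          spacing = c(1, 1, 1))
  dec <- decompose_scales(v, m, cutoff_mm = 2)
  recon <- dec$low_pass + dec$high_pass
  rng <- diff(range(v$values[m]))
  expect_lt(max(abs(recon[m] - v$values[m])), 1e-10 * rng)

  # a uniform field is pure low frequency
  u <- ventilation_volume(array(0.2, d), spacing = c(1, 1, 1))
  du <- decompose_scales(u, m, 2)
  expect_equal(du$low_pass[m], rep(0.2, sum(m)), tolerance = 1e-12)
  expect_equal(max(abs(du$high_pass[m])), 0, tolerance = 1e-12)

  # out-of-mask voxels cannot leak into in-mask averages
  v2 <- v; v2$values[!m] <- 99
  d2 <- decompose_scales(v2, m, 2)
  expect_equal(d2$low_pass[m], dec$low_pass[m], tolerance = 1e-14)

  # a single-voxel spike lands almost entirely in the high-pass component
  sp <- array(0.1, d); sp[4, 4, 4] <- 5
  ds <- decompose_scales(ventilation_volume(sp, spacing = c(1, 1, 1)),
                         array(TRUE, d), 3)
  expect_gt(var(ds$high_pass[array(TRUE, d)]), 10 * var(ds$low_pass[array(TRUE, d)]))

  expect_error(decompose_scales(v, m, 0.5), "one voxel")
})

test_that("masked Gaussian filter matches a naive per-voxel convolution", {
  for (s in 1:10) {
    cs <- random_small_case(s + 500)
    low <- decompose_scales(ventilation_volume(cs$values, spacing = c(1, 1, 1)),
                            cs$mask, cutoff_mm = 1)$low_pass
    expect_equal(low, oracle_low_pass(cs$values, cs$mask, c(1, 1, 1), 1),
                 tolerance = 1e-12)
  }
})

test_that("scale-split VH separates ramps from checkerboards", {
  d <- c(10, 10, 40)
  m <- array(TRUE, d)
  sp <- c(0.4, 0.4, 0.4)

  # uniform field: both components flat
  u <- ventilation_volume(array(0.2, d), spacing = sp)
  expect_equal(unname(compute_vh_scales(u, m, 1.2)), c(0, 0),
               tolerance = 1e-10)

  # smooth ramp over many cutoff lengths: essentially all large-scale
  ramp <- array(rep(seq(0.1, 0.4, length.out = d[3]), each = d[1] * d[2]), d)
  vr <- compute_vh_scales(ventilation_volume(ramp, spacing = sp), m, 1.2)
  expect_lt(vr[["vh_ss"]], 0.05 * vr[["vh_ls"]])

  # fine checkerboard (one-voxel wavelength): essentially all small-scale
  idx <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    idx[i, j, k] <- (i + j + k) %% 2
  chk <- 0.2 + 0.1 * (2 * idx - 1)
  vc <- compute_vh_scales(ventilation_volume(chk, spacing = sp), m, 1.2)
  expect_lt(vc[["vh_ls"]], 0.05 * vc[["vh_ss"]])
})

test_that("VH variants are invariant to positive rescaling of the field", {
  set.seed(21)
  d <- c(10, 10, 10)
  m <- array(runif(prod(d)) < 0.8, d)
  v <- array(runif(prod(d), 0.05, 0.4), d)
  for (c_mult in c(0.5, 3)) {
    expect_equal(compute_vh(c_mult * v, m), compute_vh(v, m),
                 tolerance = 1e-12)
    expect_equal(unname(compute_vh_scales(ventilation_volume(c_mult * v), m, 2)),
                 unname(compute_vh_scales(ventilation_volume(v), m, 2)),
                 tolerance = 1e-10)
  }
})

test_that("mean CT gray is the masked mean and rises with planted density", {
  d <- c(4, 4, 2)
  m <- array(TRUE, d)
  ct <- array(rep(c(100, 300), each = prod(d) / 2), d)
  expect_equal(mean_ct_gray(ct, m), 200)
  expect_equal(mean_ct_gray(array(500, d), m), 500)
  ct2 <- ct; ct2[1, 1, 1] <- 900   # denser tumor voxel, fixed mask
  expect_gt(mean_ct_gray(ct2, m), mean_ct_gray(ct, m))
})

test_that("ROI curves honor bounds, mask and phase structure", {
  vl <- virtual_lung(n_phases = 5L)
  ph <- generate_phase_series(vl, tumor_foci_spec(n_foci = 0, seed = 3))
  wl <- extract_roi_curve(ph$series, whole_lung_bounds(ph$series), "lung")

  # whole-lung ROI reproduces the whole-lung curve exactly
  for (k in seq_len(ph$series$n_phases)) {
    sv <- ph$series$volumes[[k]]$values[ph$series$mask$values]
    expect_equal(wl$phase_means[k], mean(sv))
    expect_equal(wl$phase_sds[k], sd(sv))
  }

  # single-voxel ROI has zero SDs
  idx <- which(ph$series$mask$values, arr.ind = TRUE)[1, ]
  sp <- ph$series$volumes[[1]]$spacing
  ctr <- (idx - 1) * sp
  one <- extract_roi_curve(ph$series,
                           c(ctr[1] - 0.01, ctr[1] + 0.01,
                             ctr[2] - 0.01, ctr[2] + 0.01,
                             ctr[3] - 0.01, ctr[3] + 0.01))
  expect_equal(one$n_voxels, 1L)
  expect_equal(one$phase_sds, rep(0, 5))

  expect_error(extract_roi_curve(ph$series, c(-10, -9, -10, -9, -10, -9)),
               "intersect")
})

test_that("metrics reject degenerate inputs", {
  d <- c(3, 3, 3)
  v <- array(0.1, d)
  expect_error(compute_msv(v, array(FALSE, d)), "empty lung mask")
  expect_error(compute_msv(v, array(TRUE, c(2, 2, 2))), "mismatch")
  expect_error(ventilation_volume(array(Inf, d)), "finite")
  expect_error(ventilation_volume(array(1, d), spacing = c(0, 1, 1)),
               "spacing")
})
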