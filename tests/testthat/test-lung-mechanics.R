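test_that("single-compartment simulation satisfies the equation of motion", {
  tr <- simulate_single_compartment(0.5, 0.05, noise_sd = 0)
  lhs <- tr$pressure_cmH2O
  rhs <- 0.5 * tr$flow_ml_s + tr$volume_ml / 0.05 + 3
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # r = 0: pressure in phase with volume (correlation 1 after centering)
  tr0 <- simulate_single_compartment(0, 0.05, noise_sd = 0)
  expect_equal(cor(tr0$pressure_cmH2O, tr0$volume_ml), 1, tolerance = 1e-10)

  # seeded reproducibility
  a <- simulate_single_compartment(0.5, 0.05, noise_sd = 0.1, seed = 7)
  b <- simulate_single_compartment(0.5, 0.05, noise_sd = 0.1, seed = 7)
  expect_identical(a$pressure_cmH2O, b$pressure_cmH2O)
  expect_error(simulate_single_compartment(0.5, -0.01), "must be > 0")
})

test_that("single-compartment fit recovers parameters and gates on noise", {
  tr <- simulate_single_compartment(0.5, 0.05, noise_sd = 0)
  fit <- fit_single_compartment(tr)
  expect_equal(fit$rrs, 0.5, tolerance = 1e-6)
  expect_equal(fit$crs, 0.05, tolerance = 1e-6)
  expect_equal(fit$cod, 1, tolerance = 1e-9)

  tr0 <- simulate_single_compartment(0, 0.05, noise_sd = 0)
  expect_equal(fit_single_compartment(tr0)$rrs, 0, tolerance = 1e-8)

  # heavy noise drives the coefficient of determination under the 0.9 gate
  trn <- simulate_single_compartment(0.5, 0.05, noise_sd = 10, seed = 1)
  expect_lt(fit_single_compartment(trn)$cod, 0.9)

  # collinear channels are rejected
  bad <- data.frame(time_s = 1:10, pressure_cmH2O = rnorm(10),
                    flow_ml_s = 1:10, volume_ml = 2 * (1:10))
  expect_error(fit_single_compartment(bad), "degenerate")
})

test_that("constant-phase impedance has its closed-form values", {
  cp <- constant_phase_params(rn = 0.3, i_inert = 0.005, g = 4, h = 25)
  expect_equal(cp$alpha, (2 / pi) * atan(25 / 4))

  # at f = 1/(2*pi), omega = 1 so omega^alpha = 1 for any alpha
  sp <- constant_phase_impedance(cp, 1 / (2 * pi))
  expect_equal(sp$z_real, 0.3 + 4)
  expect_equal(sp$z_imag, 0.005 - 25)

  expect_error(constant_phase_impedance(cp, c(-1, 2)), "> 0")
  expect_error(constant_phase_params(0.3, 0.005, -4, 25), "> 0")
})

test_that("constant-phase fit round-trips noiselessly and under 1% noise", {
  cp <- constant_phase_params(rn = 0.3, i_inert = 0.005, g = 4, h = 25)
  freqs <- quickprime_frequencies()
  sp <- constant_phase_impedance(cp, freqs)
  fit <- fit_constant_phase(sp)
  expect_equal(fit$rn, cp$rn, tolerance = 1e-4)
  expect_equal(fit$i_inert, cp$i_inert, tolerance = 1e-4)
  expect_equal(fit$g, cp$g, tolerance = 1e-4)
  expect_equal(fit$h, cp$h, tolerance = 1e-4)
  expect_gte(fit$cod, 0.999)

  # round trip: spectrum regenerated from the fit matches the input
  sp2 <- constant_phase_impedance(fit, freqs)
  expect_equal(sp2$z_real, sp$z_real, tolerance = 1e-6)
  expect_equal(sp2$z_imag, sp$z_imag, tolerance = 1e-6)

  # hysteresivity G/H fixes alpha under joint rescaling
  cp2 <- constant_phase_params(0.3, 0.005, 4 * 2.5, 25 * 2.5)
  expect_equal(cp2$alpha, cp$alpha)

  # 1% relative noise: median parameter error under 5% over seeded reps
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    spn <- sp
    zmag <- sqrt(sp$z_real^2 + sp$z_imag^2)
    spn$z_real <- sp$z_real + rnorm(nrow(sp), sd = 0.01 * zmag)
    spn$z_imag <- sp$z_imag + rnorm(nrow(sp), sd = 0.01 * zmag)
    f <- fit_constant_phase(spn)
    max(abs(c(f$rn - cp$rn, f$g - cp$g, f$h - cp$h)) / c(cp$rn, cp$g, cp$h))
  })
  expect_lt(median(errs), 0.05)

  expect_error(fit_constant_phase(sp[1:3, ]), "at least 4")
  expect_error(fit_constant_phase(
    constant_phase_impedance(cp, c(5, 6, 7, 8, 9))), "decade")
})

test_that("PV deflation fit recovers the exponential model", {
  pv <- simulate_pv_maneuver(1.0, 0.8, 0.1, pressures = seq(30, 0, by = -5))
  fit <- fit_pv_curve(pv$deflation)
  expect_equal(fit$a, 1.0, tolerance = 1e-6)
  expect_equal(fit$b, 0.8, tolerance = 1e-6)
  expect_equal(fit$k_curvature, 0.1, tolerance = 1e-6)
  expect_equal(fit$cst, 0.08, tolerance = 1e-6)   # C_st = B*K
  expect_gte(fit$cod, 0.999)

  # K -> 0 limit: fitted slope at 0 approaches the linear-regression slope
  p <- seq(30, 0, by = -5)
  k_small <- 1e-3
  v_lin <- 1.0 - 0.8 * exp(-k_small * p)
  ls <- unname(coef(lm(v_lin ~ p))[2])
  f2 <- fit_pv_curve(data.frame(pressure = p, volume = v_lin))
  expect_equal(f2$cst, ls, tolerance = 0.02)

  # a volume offset shifts A only, leaving C_st and K unchanged
  pv_off <- pv$deflation; pv_off$volume <- pv_off$volume + 0.5
  f3 <- fit_pv_curve(pv_off)
  expect_equal(f3$a, 1.5, tolerance = 1e-6)
  expect_equal(f3$cst, fit$cst, tolerance = 1e-6)
  expect_equal(f3$k_curvature, fit$k_curvature, tolerance = 1e-6)

  expect_error(fit_pv_curve(pv$deflation[1:4, ]), "at least 5")
  expect_error(fit_pv_curve(data.frame(pressure = c(1, 2, 1, 2, 1),
                                       volume = 1:5)), "decreasing")
})

test_that("PV loop area is the unsigned shoelace area", {
  rect <- data.frame(pressure = c(0, 10, 10, 0), volume = c(0, 0, 0.5, 0.5))
  expect_equal(pv_loop_area(rect), 5)
  expect_equal(pv_loop_area(rect[rev(seq_len(4)), ]), 5)
  flat <- data.frame(pressure = c(0, 5, 10, 5), volume = c(0, 0.2, 0.4, 0.2))
  expect_equal(pv_loop_area(flat), 0)
  expect_error(pv_loop_area(rect[1:2, ]), "at least 3")
})

test_that("NPFE metrics integrate expiratory flow with the 0.05 s split", {
  tr <- data.frame(time_s = seq(0, 0.2, by = 0.01), flow_ml_s = 10)
  np <- npfe_metrics(tr)
  expect_equal(np$fev005, 0.5)
  expect_equal(np$fvc, 2.0)
  expect_equal(np$fef005, 10)

  z <- npfe_metrics(data.frame(time_s = seq(0, 0.2, by = 0.01),
                               flow_ml_s = 0))
  expect_equal(unlist(z), c(fev005 = 0, fvc = 0, fef005 = 0))

  # fev005 <= fvc for any non-negative flow trace
  for (s in 1:20) {
    set.seed(s)
    tr2 <- data.frame(time_s = seq(0, 0.3, by = 0.005),
                      flow_ml_s = abs(rnorm(61, 10, 5)))
    np2 <- npfe_metrics(tr2)
    expect_lte(np2$fev005, np2$fvc)
  }

  # analytic check on the exponential decay used by the simulator
  sim <- simulate_npfe(q0 = 30, tau = 0.04, duration_s = 0.5, fs_hz = 5000)
  np3 <- npfe_metrics(sim)
  expect_equal(np3$fvc, 30 * 0.04 * (1 - exp(-0.5 / 0.04)), tolerance = 1e-4)
  expect_equal(np3$fev005, 30 * 0.04 * (1 - exp(-0.05 / 0.04)),
               tolerance = 1e-4)
  expect_equal(np3$fef005, 30 * exp(-0.05 / 0.04), tolerance = 1e-4)

  expect_error(npfe_metrics(data.frame(time_s = c(0, 0.01),
                                       flow_ml_s = c(1, 1))), "0.05")
})

test_that("deep-inflation IC is max volume above the PEEP baseline", {
  expect_equal(deep_inflation_ic(seq(0, 0.9, by = 0.1), peep_volume = 0.1),
               0.8)
  expect_equal(deep_inflation_ic(rep(0.3, 5), peep_volume = 0.3), 0)
  v <- seq(0, 0.9, by = 0.1)
  expect_equal(deep_inflation_ic(v + 2, peep_volume = 0.1 + 2),
               deep_inflation_ic(v, peep_volume = 0.1))
  expect_error(deep_inflation_ic(numeric(0)), "empty")
})

test_that("replicate averaging gates each parameter on its governing fit", {
  rec <- data.frame(
    ic = c(0.8, 0.9, 1.0), rrs = c(0.5, 0.6, 5.0), crs = c(0.05, 0.06, 0.5),
    rn = c(0.3, 0.3, 0.3), g = c(4, 4, 4), h = c(25, 25, 25),
    cst = c(0.08, 0.08, 0.08), k_curvature = c(0.1, 0.1, 0.1),
    pv_area = c(1.5, 1.5, 1.5), fev005 = c(0.5, 0.5, 0.5),
    fvc = c(1.2, 1.2, 1.2), fef005 = c(10, 10, 10),
    cod_single_compartment = c(0.99, 0.95, 0.80),
    cod_constant_phase = c(0.99, 0.99, 0.99),
    cod_pv = c(0.99, 0.99, 0.99))
  agg <- aggregate_replicates(rec)
  # third replicate excluded for the single-compartment parameters only
  expect_equal(agg$rrs, mean(c(0.5, 0.6)))
  expect_equal(agg$crs, mean(c(0.05, 0.06)))
  expect_equal(agg$n_single_compartment, 2)
  # ungated parameters always use all replicates
  expect_equal(agg$ic, 0.9)

  # none excluded: plain arithmetic means
  rec2 <- rec; rec2$cod_single_compartment <- c(0.99, 0.95, 0.93)
  expect_equal(aggregate_replicates(rec2)$rrs, mean(rec$rrs))

  # all excluded: missing, not zero
  rec3 <- rec; rec3$cod_single_compartment <- c(0.1, 0.2, 0.3)
  agg3 <- aggregate_replicates(rec3)
  expect_true(is.na(agg3$rrs))
  expect_true(is.na(agg3$crs))
  expect_equal(agg3$n_single_compartment, 0)

  # permutation invariance
  perm <- rec[c(3, 1, 2), ]
  expect_equal(aggregate_replicates(perm), aggregate_replicates(rec))

  expect_error(aggregate_replicates(rec[0, ]), "at least one")
})

test_that("a full simulated session reports bounded CoDs and sane values", {
  vl <- virtual_lung()
  sess <- simulate_mechanics_session(vl$mech_params, seed = 9)
  rep <- sess$replicates
  expect_true(all(rep$cod_single_compartment >= 0 &
                    rep$cod_single_compartment <= 1))
  expect_true(all(rep$cod_constant_phase >= 0 & rep$cod_constant_phase <= 1))
  expect_true(all(rep$cod_pv >= 0 & rep$cod_pv <= 1))
  expect_equal(sess$record$rrs, vl$mech_params$r, tolerance = 0.05)
  expect_equal(sess$record$crs, vl$mech_params$c, tolerance = 0.05)
  expect_equal(sess$record$h, vl$mech_params$cp$h, tolerance = 0.1)

  # trace CSV round trip
  tr <- simulate_single_compartment(0.5, 0.05, noise_sd = 0)
  f <- file.path(tempdir(), "trace.csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$pressure_cmH2O, tr$pressure_cmH2O, tolerance = 1e-9)
  unlink(f)
})
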