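## Forced-maneuver simulation and parameter estimation mirroring the
## standard small-animal ventilator battery: deep inflation (IC),
## single-compartment snapshot (R_rs, C_rs), constant-phase forced
## oscillation (R_n, G, H), stepwise pressure-volume maneuver (C_st,
## curvature, loop area) and negative-pressure forced expiration
## (FEV0.05, FVC, FEF0.05). Replicates are averaged with a coefficient of
## determination gate at 0.9.

#' Ventilator trace
#'
#' @param time seconds, strictly increasing.
#' @param pressure cmH2O.
#' @param flow ml/s.
#' @param volume ml (cumulative integral of flow; volume at time zero is 0).
#' @param maneuver one of snapshot, prime, pv, npfe, deep_inflation.
#' @return data.frame of class `ventilator_trace` with those columns.
#' @export
ventilator_trace <- function(time, pressure, flow, volume,
                             maneuver = c("snapshot", "prime", "pv", "npfe",
                                          "deep_inflation")) {
  maneuver <- match.arg(maneuver)
  n <- length(time)
  if (length(pressure) != n || length(flow) != n || length(volume) != n)
    stop("channels must have equal length")
  if (n > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  structure(
    data.frame(time_s = time, pressure_cmH2O = pressure, flow_ml_s = flow,
               volume_ml = volume, maneuver = maneuver),
    class = c("ventilator_trace", "data.frame")
  )
}

#' Constant-phase model parameters
#'
#' Tissue impedance model `Z(f) = R_n + i*2*pi*f*I + (G - iH)/(2*pi*f)^alpha`
#' with the phase exponent tied to the tissue parameters:
#' `alpha = (2/pi) * atan(H/G)`.
#'
#' @param rn Newtonian (central airway) resistance, cmH2O.s/ml.
#' @param i_inert inertance, cmH2O.s^2/ml.
#' @param g tissue damping, cmH2O/ml (> 0).
#' @param h tissue elastance, cmH2O/ml (> 0).
#' @return List of class `constant_phase_params` including `alpha`.
#' @export
constant_phase_params <- function(rn, i_inert, g, h) {
  if (!is.finite(g) || g <= 0 || !is.finite(h) || h <= 0)
    stop("g and h must be > 0")
  structure(list(rn = rn, i_inert = i_inert, g = g, h = h,
                 alpha = (2 / pi) * atan(h / g)),
            class = "constant_phase_params")
}

#' Default ventilator settings
#'
#' Respiratory rate 150 breaths/min, tidal volume 10 ml/kg (0.2 ml for a
#' 20 g mouse), PEEP 3 cmH2O, 1 kHz sampling.
#'
#' @param rate_bpm breaths per minute.
#' @param tidal_ml tidal volume in ml.
#' @param peep_cmh2o positive end-expiratory pressure.
#' @param fs_hz sampling rate.
#' @param n_breaths breaths simulated per snapshot trace.
#' @export
ventilator_settings <- function(rate_bpm = 150, tidal_ml = 0.2,
                                peep_cmh2o = 3, fs_hz = 1000, n_breaths = 3) {
  list(rate_bpm = rate_bpm, tidal_ml = tidal_ml, peep_cmh2o = peep_cmh2o,
       fs_hz = fs_hz, n_breaths = n_breaths)
}

#' Simulate a single-compartment snapshot trace
#'
#' Forward model `P(t) = r*V'(t) + V(t)/c + P0` for a sinusoidal volume
#' waveform at the ventilator rate, with optional Gaussian pressure noise.
#'
#' @param r resistance, cmH2O.s/ml (>= 0).
#' @param c compliance, ml/cmH2O (> 0).
#' @param settings a [ventilator_settings()] list.
#' @param noise_sd SD of additive Gaussian pressure noise, cmH2O.
#' @param seed optional integer seed for reproducibility.
#' @return A [ventilator_trace()] with maneuver `"snapshot"`.
#' @export
simulate_single_compartment <- function(r, c, settings = ventilator_settings(),
                                        noise_sd = 0, seed = NULL) {
  if (!is.finite(c) || c <= 0) stop("compliance c must be > 0")
  if (r < 0) stop("resistance r must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  f <- settings$rate_bpm / 60
  dur <- settings$n_breaths / f
  t <- seq(0, dur, by = 1 / settings$fs_hz)
  vol <- settings$tidal_ml / 2 * (1 - cos(2 * pi * f * t))
  flow <- settings$tidal_ml / 2 * 2 * pi * f * sin(2 * pi * f * t)
  p <- r * flow + vol / c + settings$peep_cmh2o
  if (noise_sd > 0) p <- p + rnorm(length(t), sd = noise_sd)
  ventilator_trace(t, p, flow, vol, "snapshot")
}

#' Fit the single-compartment equation of motion
#'
#' Multiple linear regression of pressure on flow and volume:
#' `P = R_rs*V' + E_rs*V + P0`, giving `C_rs = 1/E_rs`.
#'
#' @param trace a [ventilator_trace()] (or data.frame with columns
#'   `pressure_cmH2O`, `flow_ml_s`, `volume_ml`).
#' @return List with `rrs`, `crs`, `p0` and the regression `cod`
#'   (coefficient of determination).
#' @export
fit_single_compartment <- function(trace) {
  if (nrow(trace) < 3) stop("need at least 3 samples")
  X <- cbind(flow = trace$flow_ml_s, volume = trace$volume_ml)
  if (qr(cbind(1, X))$rank < 3) stop("degenerate trace: collinear channels")
  fit <- lm(trace$pressure_cmH2O ~ trace$flow_ml_s + trace$volume_ml)
  b <- unname(coef(fit))
  if (b[3] <= 0) stop("non-positive fitted elastance")
  # noiseless traces fit exactly; the perfect-fit notice is expected there
  list(rrs = b[2], crs = 1 / b[3], p0 = b[1],
       cod = suppressWarnings(summary(fit)$r.squared))
}

#' Evaluate the constant-phase impedance model
#'
#' @param params a [constant_phase_params()].
#' @param frequencies Hz, all > 0.
#' @return data.frame of class `impedance_spectrum` with columns `freq_hz`,
#'   `z_real`, `z_imag` (cmH2O.s/ml).
#' @export
constant_phase_impedance <- function(params, frequencies) {
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  w <- 2 * pi * frequencies
  z <- params$rn + 1i * w * params$i_inert +
    (params$g - 1i * params$h) / w^params$alpha
  structure(
    data.frame(freq_hz = frequencies, z_real = Re(z), z_imag = Im(z)),
    class = c("impedance_spectrum", "data.frame")
  )
}

#' Default forced-oscillation frequencies
#'
#' 13 log-spaced frequencies from 1 to 20.5 Hz, a typical mouse range.
#' @param n number of frequencies.
#' @param fmin,fmax frequency range in Hz.
#' @export
quickprime_frequencies <- function(n = 13, fmin = 1, fmax = 20.5) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Nonlinear least squares over (R_n, I, G, H) with the phase exponent tied
#' to H/G, on stacked real and imaginary residuals (Levenberg-Marquardt,
#' initialized from linearized fits of the real and imaginary parts).
#'
#' @param spectrum data.frame with columns `freq_hz`, `z_real`, `z_imag`.
#' @return A [constant_phase_params()] with an additional `cod` element
#'   (coefficient of determination over the stacked channels).
#' @export
fit_constant_phase <- function(spectrum) {
  f <- spectrum$freq_hz
  if (length(f) < 4) stop("need at least 4 frequencies")
  if (max(f) / min(f) < 10) stop("frequencies must span at least a decade")
  if (any(f <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * f
  obs <- c(spectrum$z_real, spectrum$z_imag)

  resid_fn <- function(p) {
    g <- exp(p[3]); h <- exp(p[4])
    alpha <- (2 / pi) * atan(h / g)
    zre <- p[1] + g / w^alpha
    zim <- w * p[2] - h / w^alpha
    c(zre, zim) - obs
  }

  # linearized starting values at a provisional alpha of 0.7
  a0 <- 0.7
  re_fit <- lm(spectrum$z_real ~ I(1 / w^a0))
  g0 <- max(coef(re_fit)[2], 1e-3)
  rn0 <- max(coef(re_fit)[1], 1e-4)
  im_fit <- lm(spectrum$z_imag ~ w + I(-1 / w^a0))
  i0 <- coef(im_fit)[2]
  h0 <- max(coef(im_fit)[3], 1e-3)

  fit <- minpack.lm::nls.lm(
    par = c(rn0, i0, log(g0), log(h0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop("constant-phase fit failed to converge; last residual norm ",
         format(fit$deviance), " at iterate ",
         paste(format(fit$par), collapse = ", "))
  p <- unname(fit$par)
  res <- resid_fn(p)
  cod <- 1 - sum(res^2) / sum((obs - mean(obs))^2)
  out <- constant_phase_params(rn = p[1], i_inert = p[2],
                               g = exp(p[3]), h = exp(p[4]))
  out$cod <- max(0, min(1, cod))
  out
}

#' Simulate a stepwise pressure-volume maneuver
#'
#' Deflation limb follows the exponential (Salazar-Knowles) relation
#' `V = A - B*exp(-K*P)`; the inflation limb is shifted down by a fixed
#' hysteresis offset so the loop encloses a nonzero area.
#'
#' @param a,b asymptotic and recruitable volume, ml.
#' @param k exponential shape factor, 1/cmH2O.
#' @param pressures deflation-limb pressure steps (decreasing), cmH2O.
#' @param hysteresis_ml vertical inflation/deflation separation, ml.
#' @param noise_sd Gaussian volume noise SD, ml.
#' @param seed optional seed.
#' @return List with data.frames `deflation` (pressure, volume) and `loop`
#'   (closed inflation+deflation polygon).
#' @export
simulate_pv_maneuver <- function(a, b, k, pressures = seq(30, 0, by = -3),
                                 hysteresis_ml = 0.05, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v_def <- a - b * exp(-k * pressures)
  if (noise_sd > 0) v_def <- v_def + rnorm(length(v_def), sd = noise_sd)
  p_inf <- rev(pressures)
  v_inf <- a - b * exp(-k * p_inf) - hysteresis_ml
  list(
    deflation = data.frame(pressure = pressures, volume = v_def),
    loop = data.frame(pressure = c(p_inf, pressures),
                      volume = c(v_inf, v_def))
  )
}

#' Fit the exponential deflation limb of a PV maneuver
#'
#' Fits `V = A - B*exp(-K*P)` by nonlinear least squares (initialized by a
#' log-linear fit for K). Static compliance is the slope of the fitted
#' curve at P = 0: `C_st = B*K`. The chord definition
#' `(V(P_hi) - V(P_lo)) / (P_hi - P_lo)` is available via `cst_method`.
#'
#' @param pv_points data.frame with columns `pressure` (decreasing) and
#'   `volume`; at least 5 points.
#' @param cst_method `"slope0"` (default, B*K) or `"chord"`.
#' @param chord_cmh2o pressure interval for the chord definition.
#' @return List with `a`, `b`, `k_curvature`, `cst`, `cod`.
#' @export
fit_pv_curve <- function(pv_points, cst_method = c("slope0", "chord"),
                         chord_cmh2o = c(3, 10)) {
  cst_method <- match.arg(cst_method)
  p <- pv_points$pressure; v <- pv_points$volume
  if (length(p) < 5) stop("need at least 5 deflation-limb points")
  if (any(diff(p) >= 0)) stop("deflation-limb pressures must be decreasing")
  a0 <- max(v) + 0.05 * max(diff(range(v)), 1e-6)
  lf <- lm(log(pmax(a0 - v, 1e-12)) ~ p)
  k0 <- max(-coef(lf)[2], 1e-4)
  b0 <- max(exp(coef(lf)[1]), 1e-6)
  resid_fn <- function(par) par[1] - par[2] * exp(-par[3] * p) - v
  fit <- minpack.lm::nls.lm(
    par = c(a0, b0, k0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop("PV fit failed to converge; last residual norm ",
         format(fit$deviance))
  par <- fit$par
  res <- resid_fn(par)
  cod <- 1 - sum(res^2) / sum((v - mean(v))^2)
  cst <- if (cst_method == "slope0") {
    par[2] * par[3]
  } else {
    vf <- function(pp) par[1] - par[2] * exp(-par[3] * pp)
    (vf(chord_cmh2o[2]) - vf(chord_cmh2o[1])) / diff(chord_cmh2o)
  }
  list(a = par[1], b = par[2], k_curvature = par[3], cst = cst,
       cod = max(0, min(1, cod)))
}

#' Pressure-volume loop area
#'
#' Shoelace polygon area of a closed PV loop, returned as a non-negative
#' magnitude regardless of traversal direction.
#'
#' @param loop_points data.frame with columns `pressure`, `volume` tracing
#'   the closed loop (inflation + deflation limbs).
#' @return Area in ml.cmH2O.
#' @export
pv_loop_area <- function(loop_points) {
  p <- loop_points$pressure; v <- loop_points$volume
  n <- length(p)
  if (n < 3) stop("need at least 3 points to form a loop")
  j <- c(2:n, 1)
  abs(sum(p * v[j] - p[j] * v)) / 2
}

#' Forced-expiration indices from an NPFE trace
#'
#' `fvc` is the total expired volume (trapezoidal integral of flow),
#' `fev005` the volume expired in the first 0.05 s (with exact linear
#' interpolation at the 0.05 s boundary) and `fef005` the instantaneous
#' flow at 0.05 s (linear interpolation).
#'
#' @param expiration_trace data.frame with columns `time_s` (starting at
#'   expiration onset) and `flow_ml_s` (expiratory-positive).
#' @return List with `fev005` (ml), `fvc` (ml), `fef005` (ml/s).
#' @export
npfe_metrics <- function(expiration_trace) {
  t <- expiration_trace$time_s - expiration_trace$time_s[1]
  q <- expiration_trace$flow_ml_s
  if (max(t) < 0.05) stop("trace shorter than 0.05 s")
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  fvc <- trapz(t, q)
  # split the trace exactly at t = 0.05 s
  q05 <- stats::approx(t, q, xout = 0.05)$y
  keep <- t < 0.05
  tt <- c(t[keep], 0.05); qq <- c(q[keep], q05)
  list(fev005 = trapz(tt, qq), fvc = fvc, fef005 = q05)
}

#' Simulate a negative-pressure forced expiration
#'
#' Exponentially decaying expiratory flow `Q(t) = Q0*exp(-t/tau)`, whose
#' analytic FVC is `Q0*tau`.
#'
#' @param q0 peak expiratory flow, ml/s.
#' @param tau expiratory time constant, s.
#' @param duration_s trace length.
#' @param fs_hz sampling rate.
#' @param noise_sd Gaussian flow noise SD.
#' @param seed optional seed.
#' @return data.frame with columns `time_s`, `flow_ml_s`.
#' @export
simulate_npfe <- function(q0, tau, duration_s = 0.5, fs_hz = 2000,
                          noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fs_hz)
  q <- q0 * exp(-t / tau)
  if (noise_sd > 0) q <- q + rnorm(length(t), sd = noise_sd)
  data.frame(time_s = t, flow_ml_s = q)
}

#' Inspiratory capacity from a deep-inflation maneuver
#'
#' @param volume_trace numeric vector (or data.frame with `volume_ml`)
#'   spanning the deep-inflation ramp.
#' @param peep_volume lung volume at PEEP baseline, ml.
#' @return IC in ml: maximum volume minus the PEEP baseline volume.
#' @export
deep_inflation_ic <- function(volume_trace, peep_volume = 0) {
  v <- if (is.data.frame(volume_trace)) volume_trace$volume_ml else volume_trace
  if (!length(v)) stop("empty volume trace")
  max(v) - peep_volume
}

# parameter -> governing fit (parameters without a model fit are ungated)
.param_fit_map <- c(rrs = "single_compartment", crs = "single_compartment",
                    rn = "constant_phase", g = "constant_phase",
                    h = "constant_phase",
                    cst = "pv", k_curvature = "pv", pv_area = "pv")

.mech_params <- c("ic", "rrs", "crs", "rn", "g", "h", "cst", "k_curvature",
                  "pv_area", "fev005", "fvc", "fef005")

#' Average replicate mechanics records with CoD gating
#'
#' Per parameter, averages only the replicates whose governing model fit
#' has a coefficient of determination of at least `cod_min`; a parameter
#' whose replicates are all excluded is reported as missing (`NA`), never
#' zero. Parameters not produced by a model fit (IC and the NPFE indices)
#' are always averaged. The result is invariant to the order of the
#' replicates.
#'
#' @param records data.frame with one row per replicate: the parameter
#'   columns (`ic`, `rrs`, `crs`, `rn`, `g`, `h`, `cst`, `k_curvature`,
#'   `pv_area`, `fev005`, `fvc`, `fef005`) and per-fit CoD columns
#'   `cod_single_compartment`, `cod_constant_phase`, `cod_pv`.
#' @param cod_min exclusion threshold (default 0.9; fits below it are
#'   dropped).
#' @return One-row data.frame with the averaged parameters and, per fit,
#'   the number of replicates retained (`n_single_compartment`, ...).
#' @export
aggregate_replicates <- function(records, cod_min = 0.9) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("need at least one replicate record")
  out <- list()
  for (p in .mech_params) {
    if (!p %in% names(records)) { out[[p]] <- NA_real_; next }
    vals <- records[[p]]
    fit <- .param_fit_map[p]
    keep <- if (is.na(fit)) rep(TRUE, nrow(records)) else {
      codcol <- paste0("cod_", fit)
      if (codcol %in% names(records)) records[[codcol]] >= cod_min
      else rep(TRUE, nrow(records))
    }
    keep <- keep & !is.na(vals)
    out[[p]] <- if (any(keep)) mean(vals[keep]) else NA_real_
  }
  for (fit in unique(.param_fit_map)) {
    codcol <- paste0("cod_", fit)
    out[[paste0("n_", fit)]] <-
      if (codcol %in% names(records)) sum(records[[codcol]] >= cod_min,
                                          na.rm = TRUE)
      else nrow(records)
  }
  as.data.frame(out)
}

#' Simulate and analyze one full mechanics session
#'
#' Runs the whole maneuver battery for one animal: `n_replicates`
#' replicates of snapshot, forced-oscillation, PV, NPFE and deep-inflation
#' maneuvers are simulated from the true parameters, each is fitted or
#' integrated, and the replicates are averaged under CoD gating.
#'
#' @param true_params list with elements `r`, `c` (single compartment),
#'   `cp` (a [constant_phase_params()]), `pv_a`, `pv_b`, `pv_k`,
#'   `ic`, `npfe_q0`, `npfe_tau`.
#' @param settings a [ventilator_settings()].
#' @param noise list of noise SDs: `pressure` (cmH2O), `impedance`
#'   (relative), `pv_ml`, `flow_ml_s`.
#' @param n_replicates replicates per maneuver (default 3).
#' @param seed integer seed; replicate seeds are derived from it.
#' @return List with `record` (aggregated one-row data.frame) and
#'   `replicates` (per-replicate data.frame).
#' @export
simulate_mechanics_session <- function(true_params,
                                       settings = ventilator_settings(),
                                       noise = list(pressure = 0.05,
                                                    impedance = 0.01,
                                                    pv_ml = 0.005,
                                                    flow_ml_s = 0.05),
                                       n_replicates = 3, seed = 1L) {
  freqs <- quickprime_frequencies()
  reps <- vector("list", n_replicates)
  for (j in seq_len(n_replicates)) {
    set.seed(as.integer((as.numeric(seed) * 1000 + j) %% 2147483587))
    tr <- simulate_single_compartment(true_params$r, true_params$c, settings,
                                      noise_sd = noise$pressure)
    sc <- fit_single_compartment(tr)

    spec <- constant_phase_impedance(true_params$cp, freqs)
    zmag <- sqrt(spec$z_real^2 + spec$z_imag^2)
    spec$z_real <- spec$z_real + rnorm(nrow(spec), sd = noise$impedance * zmag)
    spec$z_imag <- spec$z_imag + rnorm(nrow(spec), sd = noise$impedance * zmag)
    cp <- fit_constant_phase(spec)

    pv <- simulate_pv_maneuver(true_params$pv_a, true_params$pv_b,
                               true_params$pv_k, noise_sd = noise$pv_ml)
    pvfit <- fit_pv_curve(pv$deflation)
    area <- pv_loop_area(pv$loop)

    npfe <- simulate_npfe(true_params$npfe_q0, true_params$npfe_tau,
                          noise_sd = noise$flow_ml_s)
    np <- npfe_metrics(npfe)

    di <- data.frame(time_s = seq(0, 1, by = 0.01),
                     volume_ml = true_params$ic * seq(0, 1, by = 0.01))
    ic <- deep_inflation_ic(di, peep_volume = 0)

    reps[[j]] <- data.frame(
      ic = ic, rrs = sc$rrs, crs = sc$crs, rn = cp$rn, g = cp$g, h = cp$h,
      cst = pvfit$cst, k_curvature = pvfit$k_curvature, pv_area = area,
      fev005 = np$fev005, fvc = np$fvc, fef005 = np$fef005,
      cod_single_compartment = sc$cod, cod_constant_phase = cp$cod,
      cod_pv = pvfit$cod)
  }
  replicates <- do.call(rbind, reps)
  list(record = aggregate_replicates(replicates), replicates = replicates)
}

#' Write / read ventilator traces as CSV
#'
#' @param trace a [ventilator_trace()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  ventilator_trace(d$time_s, d$pressure_cmH2O, d$flow_ml_s, d$volume_ml,
                   d$maneuver[1])
}
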