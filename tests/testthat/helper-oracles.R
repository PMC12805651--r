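# Brute-force per-voxel oracles, written with plain loops and explicit
# formulas so they stay independent of the vectorized implementations.

oracle_msv <- function(values, mask) {
  s <- 0; n <- 0
  d <- dim(values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) { s <- s + values[i, j, k]; n <- n + 1 }
  }
  s / n
}

oracle_vt_ml <- function(values, mask, spacing) {
  s <- 0
  d <- dim(values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) s <- s + values[i, j, k]
  }
  s * spacing[1] * spacing[2] * spacing[3] / 1000
}

oracle_vdp <- function(values, mask, tf, ref) {
  below <- 0; n <- 0
  d <- dim(values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) {
      n <- n + 1
      if (values[i, j, k] < tf * ref) below <- below + 1
    }
  }
  100 * below / n
}

# linearly interpolated quantile (the type-7 rule) written from scratch
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_vh <- function(values, mask) {
  sv <- c()
  d <- dim(values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) sv <- c(sv, values[i, j, k])
  }
  (oracle_quantile7(sv, 0.75) - oracle_quantile7(sv, 0.25)) / mean(sv)
}

# naive separable masked Gaussian low-pass: per-axis loops over kernel taps
oracle_low_pass <- function(values, mask, spacing, cutoff_mm) {
  num <- values * mask
  den <- mask * 1
  d <- dim(values)
  for (ax in 1:3) {
    s <- cutoff_mm / spacing[ax]
    r <- max(1, ceiling(4 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2)); w <- w / sum(w)
    new_num <- array(0, d); new_den <- array(0, d)
    for (tap in seq_along(w)) {
      off <- tap - r - 1
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        src <- c(i, j, k); src[ax] <- src[ax] - off
        if (src[ax] >= 1 && src[ax] <= d[ax]) {
          new_num[i, j, k] <- new_num[i, j, k] + w[tap] * num[src[1], src[2], src[3]]
          new_den[i, j, k] <- new_den[i, j, k] + w[tap] * den[src[1], src[2], src[3]]
        }
      }
    }
    num <- new_num; den <- new_den
  }
  low <- array(0, d)
  low[mask] <- num[mask] / den[mask]
  low
}

# Welch t-test from the textbook formulas
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson r and its two-sided p from the closed-form t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# small random volume/mask pair for oracle comparisons
random_small_case <- function(seed, max_dim = 5) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  vals <- array(runif(prod(d), 0.01, 0.5), d)
  m <- array(runif(prod(d)) < 0.7, d)
  if (!any(m)) m[1, 1, 1] <- TRUE
  list(values = vals, mask = m, dim = d)
}
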