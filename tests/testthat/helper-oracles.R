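# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (explicit loops, literal formulas)
# so it cannot share a defect with the vectorized package code.

# O(n^2) pair-by-pair semivariogram: the method-of-moments estimator
# written as a plain double loop with its own binning.
brute_semivariogram <- function(coords, values, bin_width, max_lag,
                                min_pairs = 1L) {
  n <- nrow(coords)
  nbins <- ceiling(max_lag / bin_width)
  ss <- numeric(nbins); np <- integer(nbins); dsum <- numeric(nbins)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      h <- sqrt((coords[i, 1] - coords[j, 1])^2 +
                (coords[i, 2] - coords[j, 2])^2)
      if (h <= 0 || h > max_lag) next
      b <- ceiling(h / bin_width)
      if (b > nbins) b <- nbins
      ss[b] <- ss[b] + (values[i] - values[j])^2
      np[b] <- np[b] + 1L
      dsum[b] <- dsum[b] + h
    }
  }
  keep <- np >= min_pairs
  data.frame(lag = dsum[keep] / np[keep],
             gamma = ss[keep] / (2 * np[keep]),
             np = np[keep])[order(dsum[keep] / np[keep]), ]
}

# Exponential semivariance written out literally (used by the kriging
# oracle so it does not depend on model_gamma()).
exp_gamma_literal <- function(c0, c, a, h) {
  ifelse(h == 0, 0, c0 + c * (1 - exp(-3 * h / a)))
}

# Ordinary kriging by explicit matrix inversion of the full augmented
# system, built element by element.
oracle_ok <- function(coords, values, target, c0, c, a) {
  n <- nrow(coords)
  A <- matrix(0, n + 1L, n + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      A[i, j] <- exp_gamma_literal(c0, c, a, h)
    }
  }
  A[n + 1L, seq_len(n)] <- 1
  A[seq_len(n), n + 1L] <- 1
  b <- numeric(n + 1L)
  for (i in seq_len(n)) {
    h <- sqrt(sum((coords[i, ] - target)^2))
    b[i] <- exp_gamma_literal(c0, c, a, h)
  }
  b[n + 1L] <- 1
  sol <- solve(A) %*% b
  list(estimate = sum(sol[seq_len(n)] * values),
       weights = sol[seq_len(n)])
}

sample_skewness <- function(x) {
  m <- mean(x); s <- sd(x)
  mean((x - m)^3) / s^3
}

# Minimal wells table from raw vectors (bypasses the simulator).
make_wells <- function(conc, x = seq_along(conc) * 100,
                       y = rep(0, length(conc))) {
  structure(data.frame(well_id = sprintf("W%05d", seq_along(conc)),
                       x = x, y = y, conc_ugL = conc,
                       censored = rep(FALSE, length(conc)),
                       stringsAsFactors = FALSE),
            class = c("wells", "data.frame"))
}

# Smooth two-bump surface on [-1, 1]^2 used as a learnable target.
two_bumps <- function(x, y) {
  exp(-((x - 0.4)^2 + (y - 0.4)^2) / 0.1) +
    exp(-((x + 0.4)^2 + (y + 0.4)^2) / 0.15)
}

# A quick strongly structured synthetic survey for CV tests.
structured_wells <- function(n, seed, nugget = 0.005, psill = 0.05,
                             range_m = 15000, log_mean = 0.5) {
  fs <- field_spec(variogram_model("exponential", nugget, psill, range_m),
                   log_mean = log_mean, extent = c(0, 30000, 0, 25000),
                   seed = seed)
  simulate_wells(fs, n, seed = seed + 1L)
}
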