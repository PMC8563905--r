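# Independent oracles, kept deliberately naive so they share no code with
# the implementation paths they check.

# Brute-force Pearson correlation at every integer lag in [-L, L], truncated
# overlap, one cor() call per lag.
brute_lag_curve <- function(x, y, L) {
  n <- length(x)
  vapply((-L):L, function(k) {
    if (k >= 0) {
      xs <- x[1:(n - k)]; ys <- y[(1 + k):n]
    } else {
      xs <- x[(1 - k):n]; ys <- y[1:(n + k)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
  }, numeric(1))
}

# Analytic amplitude gain of an order-`ord` digital (bilinear, prewarped)
# Butterworth low-pass applied forward and backward.
butter_gain_digital <- function(f_hz, fs_hz, fc_hz, ord) {
  1 / (1 + (tan(pi * f_hz / fs_hz) / tan(pi * fc_hz / fs_hz))^(2 * ord))
}

# Analog-prototype gain (valid far below Nyquist), same convention.
butter_gain_analog <- function(f_hz, fc_hz, ord) {
  1 / (1 + (f_hz / fc_hz)^(2 * ord))
}

# Steady-state amplitude of a sinusoid in a filtered trace, discarding the
# edge-affected margins.
steady_amplitude <- function(ts, margin_s = 1) {
  t <- oromotor::ts_time(ts)
  keep <- t > t[1] + margin_s & t < t[length(t)] - margin_s
  (max(ts$values[keep]) - min(ts$values[keep])) / 2
}

# Closed-form paired t statistic and two-sided p for a difference vector.
closed_form_paired_t <- function(d) {
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), n - 1))
}

# Exhaustive per-cycle argmax of the first difference of a trace restricted
# to each given cycle window; the derivative-peak oracle for lick onsets.
brute_cycle_derivative_argmax <- function(y, rate_hz, cycle_starts, period_s) {
  d <- diff(y)
  td <- (seq_along(d) - 0.5) / rate_hz
  vapply(cycle_starts, function(cs) {
    idx <- which(td >= cs & td < cs + period_s)
    td[idx[which.max(d[idx])]]
  }, numeric(1))
}
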