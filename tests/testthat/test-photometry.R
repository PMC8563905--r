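test_that("resampling preserves constants and evaluates sinusoids at grid points", {
  const <- ts_signal(rep(3.3, 2401), 1200, 0)   # 2 s at 1200 Hz
  r <- resample_ts(const, 120)
  expect_equal(length(r), 241L)
  expect_equal(r$rate_hz, 120)
  expect_true(all(abs(r$values - 3.3) < 1e-12))

  sine <- make_sine_ts(1, 1200, 10)
  r2 <- resample_ts(sine, 120)
  expect_equal(length(r2), 1201L)
  expect_lt(max(abs(r2$values - sin(2 * pi * ts_time(r2)))), 1e-3)

  expect_error(resample_ts(sine, 0), "positive")
})

test_that("low-pass filter is DC-transparent and matches its analytic magnitude response", {
  const <- ts_signal(rep(2.5, 600), 120, 0)
  out <- lowpass_ts(const, 20, 2)
  expect_lt(max(abs(out$values - 2.5)), 1e-9)
  expect_equal(length(out), length(const))

  # passband: 1 Hz sinusoid essentially untouched
  s1 <- make_sine_ts(1, 120, 10)
  a1 <- steady_amplitude(lowpass_ts(s1, 20, 2))
  expect_gte(a1, 0.99)

  # stopband at 50 Hz on a 120 Hz grid: the bilinear-design response
  # (frequency-warped near Nyquist) is the correct analytic reference
  s50 <- make_sine_ts(50, 120, 10)
  a50 <- steady_amplitude(lowpass_ts(s50, 20, 2))
  expect_lt(abs(a50 / butter_gain_digital(50, 120, 20, 2) - 1), 0.10)

  # far below Nyquist the analog closed form 1/(1+(f/fc)^4) applies:
  # 50 Hz on a 1200 Hz grid, expected amplitude ~0.0250
  s50hr <- make_sine_ts(50, 1200, 10)
  a50hr <- steady_amplitude(lowpass_ts(s50hr, 20, 2))
  expect_lt(abs(a50hr / butter_gain_analog(50, 20, 2) - 1), 0.10)

  expect_error(lowpass_ts(s1, 60), "Nyquist")
})

test_that("filtering is zero-phase: low-frequency sinusoid is not delayed", {
  s <- make_sine_ts(2, 120, 10)
  f <- lowpass_ts(s, 20, 2)
  keep <- 121:1080   # discard edge-affected seconds
  lags <- -10:10
  cc <- vapply(lags, function(k) {
    n <- length(keep)
    stats::cor(s$values[keep][1:(n - abs(k))],
               f$values[keep + k][1:(n - abs(k))])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("isosbestic OLS recovers exact affine relations and noisy slopes", {
  ramp <- ts_signal(seq(1, 5, length.out = 1000), 120, 0)
  f465 <- ts_signal(2 + 3 * ramp$values, 120, 0)
  fit <- fit_isosbestic_baseline(f465, ramp)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$f0$values, f465$values, tolerance = 1e-12)

  # slope of F465 = 5 * F405 + N(0, 0.01^2): OLS sd is well below 0.01
  set.seed(42)
  x <- runif(1e4, 1, 2)
  y <- 5 * x + rnorm(1e4, 0, 0.01)
  fit2 <- fit_isosbestic_baseline(ts_signal(y, 120), ts_signal(x, 120))
  expect_lt(abs(fit2$slope - 5), 0.01)

  const <- ts_signal(rep(1, 1000), 120, 0)
  expect_error(fit_isosbestic_baseline(f465, const), "constant")
})

test_that("dF/F is the elementwise fractional change and rejects bad baselines", {
  ramp <- ts_signal(seq(2, 4, length.out = 500), 120, 0)
  fit <- fit_isosbestic_baseline(ramp, ramp)
  dff0 <- compute_dff(ramp, fit)
  expect_lt(max(abs(dff0$values)), 1e-10)

  f12 <- ts_signal(1.2 * fit$f0$values, 120, 0)
  expect_equal(compute_dff(f12, fit)$values, rep(0.2, 500), tolerance = 1e-12)

  bad <- fit
  bad$f0$values[7] <- 0
  expect_error(compute_dff(ramp, bad), "sample 7")
})

test_that("exact affine 465/405 relation yields identically zero dF/F through the full pipeline", {
  t <- seq(0, 20, by = 1 / 1200)
  c405 <- 80 * exp(-t / 300) + 0.5 * sin(2 * pi * 0.2 * t)
  f465 <- 10 + 1.25 * c405
  proc <- process_photometry(ts_signal(f465, 1200), ts_signal(c405, 1200))
  expect_lt(max(abs(proc$dff$values)), 1e-10)
  expect_identical(proc$provenance$stages,
                   c("resample", "lowpass", "fit_isosbestic_baseline",
                     "compute_dff"))
})

test_that("isosbestic correction rejects motion artifacts by >= 10x across seeds", {
  ratios <- vapply(1:20, function(s) {
    cfg <- generator_config(duration_s = 30, seed = s,
                            kernel = calcium_kernel(amplitude = 0),
                            noise_sd = 0, motion_amp = 2, bleach_tau_s = Inf,
                            bout_structure = data.frame(start_s = numeric(0),
                                                        n_licks = integer(0)))
    ses <- generate_session(cfg)
    proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
    # uncorrected: (F - mean)/mean on the same resampled, filtered channel
    r465 <- lowpass_ts(resample_ts(ses$photometry$f465, 120), 20, 2)
    uncorr <- (r465$values - mean(r465$values)) / mean(r465$values)
    max(abs(uncorr)) / max(abs(proc$dff$values))
  }, numeric(1))
  expect_true(all(ratios >= 10))
})

test_that("motion-only sessions leave dF/F uncorrelated with the injected motion trace", {
  ok <- vapply(1:100, function(s) {
    cfg <- generator_config(duration_s = 120, seed = s,
                            kernel = calcium_kernel(amplitude = 0),
                            motion_amp = 2,
                            bout_structure = data.frame(start_s = numeric(0),
                                                        n_licks = integer(0)))
    ses <- generate_session(cfg)
    proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
    m120 <- resample_ts(ses$motion, 120)
    abs(stats::cor(proc$dff$values, m120$values)) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the mean-ratio baseline variant is exposed and differs from OLS", {
  t <- seq(0, 10, by = 1 / 120)
  c405 <- ts_signal(80 + sin(2 * pi * 0.3 * t), 120)
  f465 <- ts_signal(30 + 1.1 * c405$values, 120)
  ols <- fit_isosbestic_baseline(f465, c405, method = "ols")
  scl <- fit_isosbestic_baseline(f465, c405, method = "scale")
  expect_equal(ols$intercept, 30, tolerance = 1e-8)
  expect_identical(scl$intercept, 0)
  expect_equal(scl$slope, mean(f465$values) / mean(c405$values))
  expect_gt(scl$rss, ols$rss)
})
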