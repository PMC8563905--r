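test_that("contact regressor is binary on the analysis grid with bounds checking", {
  reg <- contact_regressor(event_series(0.5), 120, 1)
  expect_length(reg$values, 121L)
  expect_equal(which(reg$values == 1), 61L)   # frame containing t = 0.5 s
  expect_equal(sum(reg$values), 1)

  none <- contact_regressor(event_series(numeric(0)), 120, 1)
  expect_true(all(none$values == 0))
  expect_true(attr(none, "no_contacts"))

  expect_error(contact_regressor(event_series(1.5), 120, 1), "outside")
})

test_that("lag curve equals the brute-force Pearson oracle to 1e-10 on 30 s sessions", {
  ses <- generate_session(noisy_config(30, seed = 9))
  proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
  reg <- contact_regressor(ses$photometry$contacts, 120, ts_duration(proc$dff))
  cur <- lag_correlation_curve(proc$dff, reg, 10)
  oracle <- brute_lag_curve(reg$values, proc$dff$values, 1200L)
  expect_equal(length(cur$r), 2401L)
  expect_lt(max(abs(cur$r - oracle)), 1e-10)
  expect_true(all(abs(cur$r) <= 1))
  expect_true(all(diff(cur$lags_s) > 0))
  expect_equal(cur$lags_s, -rev(cur$lags_s))   # symmetric grid
})

test_that("self-correlation peaks at lag zero and a planted shift is recovered exactly", {
  set.seed(4)
  v <- as.numeric(stats::filter(rnorm(3600), rep(1 / 5, 5), sides = 2))
  v[is.na(v)] <- 0
  x <- ts_signal(v, 120, 0)
  self <- lag_correlation_curve(x, x, 2)
  m <- curve_max(self)
  expect_equal(m$max_lag_s, 0)
  expect_equal(m$max_r, 1, tolerance = 1e-12)

  # dff equal to the regressor delayed by 25 samples
  y <- ts_signal(c(rep(0, 25), v[1:(3600 - 25)]), 120, 0)
  cur <- lag_correlation_curve(y, x, 2)
  expect_equal(curve_max(cur)$max_lag_s, 25 / 120, tolerance = 1e-12)
  oracle <- brute_lag_curve(x$values, y$values, 240L)
  expect_lt(max(abs(cur$r - oracle)), 1e-10)
})

test_that("swapping the two series mirrors the lag axis", {
  set.seed(5)
  a <- ts_signal(rnorm(2000), 100, 0)
  b <- ts_signal(rnorm(2000), 100, 0)
  ab <- lag_correlation_curve(b, a, 3)
  ba <- lag_correlation_curve(a, b, 3)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("independent white-noise series rarely exceed |r| = 0.1 anywhere", {
  ok <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    a <- ts_signal(rnorm(120 * 120), 120, 0)
    b <- ts_signal(rnorm(120 * 120), 120, 0)
    max(abs(lag_correlation_curve(a, b, 10)$r)) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("circular rotation preserves the regressor value multiset exactly", {
  ses <- generate_session(noisy_config(30, seed = 2))
  proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
  dur <- ts_duration(proc$dff)
  reg <- contact_regressor(ses$photometry$contacts, 120, dur)
  n <- length(reg$values)
  # reproduce the internal rotation and check the multiset directly
  for (off in c(1200, 1800, 2400)) {
    rot <- c(reg$values[(n - off + 1):n], reg$values[1:(n - off)])
    expect_identical(sort(rot), sort(reg$values))
    expect_identical(sum(rot), sum(reg$values))
    expect_equal(stats::var(rot), stats::var(reg$values), tolerance = 1e-15)
  }
  # fixed seed reproduces the null curve bit-for-bit
  n1 <- shuffled_null_curve(proc$dff, ses$photometry$contacts, 5, seed = 77,
                            max_lag_s = 5)
  n2 <- shuffled_null_curve(proc$dff, ses$photometry$contacts, 5, seed = 77,
                            max_lag_s = 5)
  expect_identical(n1$r, n2$r)
  expect_true(n1$is_null)
})

test_that("planted coupling beats the shuffled null in nearly all seeds", {
  ok <- vapply(1:50, function(s) {
    ses <- generate_session(noisy_config(30, seed = 100 + s))
    proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
    reg <- contact_regressor(ses$photometry$contacts, 120,
                             ts_duration(proc$dff))
    real <- curve_max(lag_correlation_curve(proc$dff, reg, 5))$max_r
    nul <- curve_max(shuffled_null_curve(proc$dff, ses$photometry$contacts,
                                         5, seed = s, max_lag_s = 5))$max_r
    real > nul
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("animal summaries average pointwise and break maximum ties toward small lags", {
  ses <- generate_session(noisy_config(25, seed = 3))
  proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
  reg <- contact_regressor(ses$photometry$contacts, 120, ts_duration(proc$dff))
  cur <- lag_correlation_curve(proc$dff, reg, 5)
  nul <- shuffled_null_curve(proc$dff, ses$photometry$contacts, 3, seed = 1,
                             max_lag_s = 5)
  s2 <- summarize_animal(list(cur, cur), list(nul), "m1")
  expect_equal(s2$mean_curve$r, cur$r)
  expect_equal(s2$max_r, curve_max(cur)$max_r)

  # a flat curve resolves its maximum at lag 0 by the tie rule
  flat <- cur
  flat$r <- rep(0.3, length(flat$r))
  expect_equal(curve_max(flat)$max_lag_s, 0)
  expect_equal(curve_max(flat)$max_r, 0.3)

  short <- lag_correlation_curve(proc$dff, reg, 4)
  expect_error(summarize_animal(list(cur, short), list(nul)), "grid")
})

test_that("paired test matches the closed-form t statistic and rejects degenerate input", {
  mk <- function(d) {
    structure(list(max_r = 0.3 + d, null_max_r = 0.3,
                   max_lag_s = 1, null_max_lag_s = 0),
              class = "animal_corr_summary")
  }
  diffs <- c(0.2, 0.25, 0.18, 0.22)
  res <- paired_shift_test(lapply(diffs, mk))
  oracle <- closed_form_paired_t(diffs)
  expect_equal(res$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n, 4L)

  expect_error(paired_shift_test(lapply(rep(0.1, 3), mk)), "degenerate")
  expect_error(paired_shift_test(list(mk(0.1))), "at least 2")
})

test_that("planted delays of 0.5, 1.2 and 3 s are recovered within 0.05 s", {
  hits <- unlist(lapply(c(0.5, 1.2, 3.0), function(d) {
    vapply(1:8, function(s) {
      cfg <- generator_config(duration_s = 60, seed = 500 + s,
                              contact_to_peak_delay_s = d)
      ses <- generate_session(cfg)
      proc <- process_photometry(ses$photometry$f465, ses$photometry$f405)
      reg <- contact_regressor(ses$photometry$contacts, 120,
                               ts_duration(proc$dff))
      abs(curve_max(lag_correlation_curve(proc$dff, reg, 10))$max_lag_s - d) <=
        0.05
    }, logical(1))
  }))
  expect_gte(mean(hits), 0.90)
})

test_that("the pipeline wrapper returns per-animal summaries and the paired test", {
  bundles <- unlist(lapply(1:2, function(a) lapply(1:2, function(s)
    generate_session(noisy_config(25, seed = a * 10 + s),
                     session_id = paste0("s", s),
                     animal_id = paste0("a", a)))), recursive = FALSE)
  res <- run_correlation_pipeline(bundles, max_lag_s = 5, n_shuffles = 2,
                                  seed = 3)
  expect_length(res$animal_summaries, 2L)
  expect_s3_class(res$grand_mean_curve, "lag_corr_curve")
  expect_true(is.numeric(res$test$p_value))
  expect_equal(res$test$n, 2L)
  # planted latency visible in the grand mean
  expect_lt(abs(curve_max(res$grand_mean_curve)$max_lag_s - 1.2), 0.05)
})

test_that("sessions shorter than twice the maximum lag are rejected", {
  x <- ts_signal(rnorm(1000), 120, 0)
  expect_error(lag_correlation_curve(x, x, 10), "twice")
})
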