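test_that("calibration converts pixels to mm linearly and smoothing preserves cubics", {
  n <- 200
  tr <- pose_track(rep(0, n), c(rep(0, 100), rep(40, 100)), rep(0.99, n), 120)
  cal <- calibrate_and_smooth(tr, scale_bar_px = 100)
  # 40 px under a 100 px / 5 mm bar is 2.0 mm (plateau means avoid the
  # smoothing overshoot at the step itself)
  expect_equal(mean(cal$y[150:200]) - mean(cal$y[1:50]), 2.0,
               tolerance = 1e-6)

  # doubling the scale bar halves the mm values
  cal2 <- calibrate_and_smooth(tr, scale_bar_px = 200)
  expect_equal(cal2$y, cal$y / 2, tolerance = 1e-12)

  # a cubic trajectory passes through order-3 smoothing unchanged
  t <- (0:199) / 120
  cub <- 1 + 2 * t - 3 * t^2 + 0.7 * t^3
  tr3 <- pose_track(rep(0, 200), cub, rep(0.99, 200), 120)
  cal3 <- calibrate_and_smooth(tr3, scale_bar_px = 5)   # mm == px here
  expect_lt(max(abs(cal3$y - cub)[6:195]), 1e-9)

  expect_error(calibrate_and_smooth(tr, 100, window = 4), "odd")
  expect_error(calibrate_and_smooth(tr, 100, window = 301), "shorter")
})

test_that("pre-stimulus baseline normalization subtracts the 50-100 ms window mean", {
  rate <- 120
  y <- c(rep(10, 120), rep(14, 120))   # step at t = 1 s
  tr <- pose_track(rep(0, 240), y, rep(0.99, 240), rate, units = "px")
  out <- normalize_baseline(tr, "prestim",
                            stim_onsets = event_series(1.0, "stim_onset"))
  expect_equal(out$y[1:100], rep(0, 100))
  expect_equal(out$y[150:240], rep(4, 91))
  expect_error(normalize_baseline(tr, "prestim"), "requires")
})

test_that("quiescent baseline uses still stretches of 1-3 s and errors when none exist", {
  rate <- 120
  t <- (0:599) / rate
  y <- rep(2.0, 600)
  y[200:320] <- 2.0 + sin(2 * pi * 7 * t[200:320])   # a moving stretch
  tr <- pose_track(rep(0, 600), y, rep(0.99, 600), rate, units = "mm")
  out <- normalize_baseline(tr, "quiescent")
  expect_equal(attr(out, "baseline_mm"), 2.0, tolerance = 1e-9)
  expect_equal(out$y[1:100], rep(0, 100), tolerance = 1e-9)

  never_still <- pose_track(rep(0, 600), sin(2 * pi * 7 * t) * 3,
                            rep(0.99, 600), rate, units = "mm")
  expect_error(normalize_baseline(never_still, "quiescent"), "quiescent")
})

test_that("tongue gating replaces low-likelihood frames and is idempotent", {
  lik <- c(rep(0.02, 50), rep(0.95, 30), rep(0.03, 40))
  y <- c(rep(5, 50), seq(5, 9, length.out = 30), rep(99, 40))
  tr <- pose_track(rep(0, 120), y, lik, 120, "tongue", "mm")
  g <- gate_tongue(tr)
  expect_equal(attr(g, "baseline"), 5)        # frame preceding first protrusion
  expect_true(all(g$y[lik < 0.05] == 5))
  expect_equal(g$y[lik >= 0.05], y[lik >= 0.05])
  expect_false(attr(g, "tongue_never_detected"))

  g2 <- gate_tongue(g)
  expect_identical(g2$y, g$y)

  allbad <- pose_track(rep(0, 50), rnorm(50, 7), rep(0.01, 50), 120,
                       "tongue", "mm")
  gal <- gate_tongue(allbad)
  expect_true(attr(gal, "tongue_never_detected"))
  expect_true(all(gal$y == attr(gal, "baseline")))
})

test_that("lick onsets match the exhaustive per-cycle derivative argmax", {
  rate <- 120
  period <- 1 / 7
  starts <- c(0.500, 0.643, 0.786)
  t <- (0:239) / rate
  y <- rep(0, 240)
  for (cs in starts) {
    idx <- which(t >= cs & t < cs + period)
    y[idx] <- (1 - cos(2 * pi * (t[idx] - cs) / period)) / 2
  }
  tr <- pose_track(rep(0, 240), y, rep(0.99, 240), rate, units = "mm")
  ons <- detect_lick_onsets(tr)
  expect_length(ons$times_s, 3L)
  oracle <- brute_cycle_derivative_argmax(y, rate, starts, period)
  expect_true(all(abs(ons$times_s - oracle) <= 1 / rate + 1e-9))

  flat <- pose_track(rep(0, 240), rep(1, 240), rep(0.99, 240), rate)
  expect_length(detect_lick_onsets(flat)$times_s, 0L)

  step <- pose_track(rep(0, 240), c(rep(0, 120), rep(1, 120)),
                     rep(0.99, 240), rate)
  expect_length(detect_lick_onsets(step)$times_s, 1L)
})

test_that("onset count matches the planted cycle count across generator seeds", {
  ok <- vapply(1:20, function(s) {
    cfg <- generator_config(duration_s = 12, seed = s,
                            bout_structure = data.frame(
                              start_s = c(2, 7), n_licks = c(8L, 5L)))
    pose <- generate_pose(cfg)
    cal <- calibrate_and_smooth(pose$jaw, cfg$scale_bar_px)
    length(detect_lick_onsets(cal)$times_s) == 13L
  }, logical(1))
  expect_true(all(ok))
})

test_that("bout segmentation separates bouts from unitary licking events", {
  ons <- event_series(c(1.00, 1.14, 1.28, 5.00), "lick_onset")
  sb <- segment_bouts(ons)
  expect_length(sb$bouts, 1L)
  expect_equal(sb$bouts[[1]]$n, 3L)
  expect_equal(sb$unitary$times_s, 5.00)

  empty <- segment_bouts(event_series(numeric(0), "lick_onset"))
  expect_length(empty$bouts, 0L)
  expect_length(empty$unitary$times_s, 0L)

  sparse <- segment_bouts(event_series(c(1, 2, 3, 4), "lick_onset"))
  expect_length(sparse$bouts, 0L)
  expect_length(sparse$unitary$times_s, 4L)
})

test_that("frequency estimators behave as defined on periodic bouts", {
  b <- lick_bout(seq(0, by = 1 / 7, length.out = 8))   # span exactly 1 s
  expect_equal(lick_frequency(b, "interval"), 7, tolerance = 1e-12)
  expect_equal(lick_frequency(b, "count_over_span"), 8, tolerance = 1e-12)

  b2 <- lick_bout(c(0, 0.2))
  expect_equal(lick_frequency(b2, "interval"), 5)

  expect_error(lick_bout(0.3), "at least 2")

  # interval estimator equals the reciprocal mean inter-lick interval
  set.seed(2)
  tt <- cumsum(runif(9, 0.1, 0.2))
  b3 <- lick_bout(tt)
  expect_equal(lick_frequency(b3, "interval"), 1 / mean(diff(tt)),
               tolerance = 1e-12)
})
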