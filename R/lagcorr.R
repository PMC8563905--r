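#' Binary lick-contact regressor on the analysis grid
#'
#' Converts capacitance-sensor contact times into a binary series at the
#' analysis rate: 1 in the frame containing each contact, 0 elsewhere.
#'
#' @param contacts an [event_series()] of contact times.
#' @param rate_hz analysis rate (default 120 Hz).
#' @param duration_s session span; output has
#'   `floor(duration_s * rate_hz) + 1` samples.
#' @return a [ts_signal()]; attribute `"no_contacts"` is `TRUE` when the
#'   series is all zero (downstream correlation would be degenerate).
#' @export
contact_regressor <- function(contacts, rate_hz = 120, duration_s) {
  stopifnot(inherits(contacts, "event_series"))
  if (rate_hz <= 0) stop("rate_hz must be positive")
  ct <- contacts$times_s
  if (length(ct) && (min(ct) < 0 || max(ct) > duration_s))
    stop("contact outside [0, duration_s]")
  n <- floor(duration_s * rate_hz + 1e-9) + 1L
  v <- numeric(n)
  if (length(ct)) {
    idx <- pmin(n, floor(ct * rate_hz + 1e-9) + 1L)
    v[idx] <- 1
  }
  out <- ts_signal(v, rate_hz, 0)
  attr(out, "no_contacts") <- length(ct) == 0L
  out
}

# internal: Pearson correlation at every integer shift k in [-L, L] with
# truncated (non-wrapped) overlap. Positive k correlates x[1:(n-k)] with
# y[(1+k):n], i.e. y lagging x by k samples. Uses an FFT cross-correlation
# for the product sums and cumulative sums for the windowed moments, so the
# whole curve costs O(n log n) instead of O(n * lags).
lag_pearson_all <- function(x, y, L) {
  n <- length(x)
  stopifnot(length(y) == n, L < n)
  N <- stats::nextn(2L * n - 1L, 2)
  fx <- stats::fft(c(x, numeric(N - n)))
  fy <- stats::fft(c(y, numeric(N - n)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / N
  # cc[1 + k] = sum_i x[i] y[i+k] for k >= 0; cc[N + 1 + k] for k < 0
  ks <- (-L):L
  sxy <- ifelse(ks >= 0, cc[1L + pmax(ks, 0)], cc[N + 1L + pmin(ks, 0)])
  Px <- cumsum(x);  Px2 <- cumsum(x^2)
  Py <- cumsum(y);  Py2 <- cumsum(y^2)
  m <- n - abs(ks)
  pos <- ks > 0; neg <- ks < 0; zero <- ks == 0
  sx <- sx2 <- sy <- sy2 <- numeric(length(ks))
  # k >= 0: overlap is x[1:(n-k)] with y[(1+k):n]
  sx[!neg]  <- Px[m[!neg]];   sx2[!neg] <- Px2[m[!neg]]
  sy[pos]   <- Py[n] - Py[ks[pos]]
  sy2[pos]  <- Py2[n] - Py2[ks[pos]]
  sy[zero]  <- Py[n];         sy2[zero] <- Py2[n]
  # k < 0: overlap is x[(1-k):n] with y[1:(n+k)]
  sx[neg]   <- Px[n] - Px[-ks[neg]]
  sx2[neg]  <- Px2[n] - Px2[-ks[neg]]
  sy[neg]   <- Py[m[neg]];    sy2[neg]  <- Py2[m[neg]]
  num <- m * sxy - sx * sy
  vx <- m * sx2 - sx^2
  vy <- m * sy2 - sy^2
  # guard tiny negative values from roundoff, and flag constant segments
  scale_x <- max(sx2[ks == 0], 1)
  scale_y <- max(sy2[ks == 0], 1)
  const <- vx <= 1e-10 * m * scale_x | vy <= 1e-10 * m * scale_y
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(const | den == 0, 0, num / den)
  r <- pmin(1, pmax(-1, r))
  list(lags = ks, r = r, n_used = m, flagged_constant = const)
}

#' Lagged Pearson correlation curve between dF/F and a lick regressor
#'
#' For every integer shift of the dF/F trace over `-max_lag_s` to
#' `+max_lag_s` (1/rate steps; 2401 lags at the defaults), the Pearson
#' correlation of the overlapping, truncated (non-wrapped) segments of the
#' two series. Positive lag means the calcium signal follows lick-port
#' contact. Segments that are constant at some lag yield r = 0 and are
#' flagged. Per-lag overlap sample counts are retained.
#'
#' @param dff the dF/F trace, a [ts_signal()].
#' @param regressor the contact regressor on the same grid.
#' @param max_lag_s maximum shift in seconds (default 10).
#' @param session_id identifier carried into the curve.
#' @param is_null flag marking shuffled-null curves.
#' @return object of class `lag_corr_curve`: list with `lags_s`, `r`,
#'   `n_used`, `flagged_constant`, `session_id`, `is_null`, `rate_hz`.
#' @export
lag_correlation_curve <- function(dff, regressor, max_lag_s = 10,
                                  session_id = NA_character_,
                                  is_null = FALSE) {
  stopifnot(inherits(dff, "ts_signal"), inherits(regressor, "ts_signal"))
  if (!same_grid(dff, regressor))
    stop("dff and regressor must share the same sampling grid")
  rate <- dff$rate_hz
  L <- round(max_lag_s * rate)
  n <- length(dff$values)
  if (n <= 2 * L)
    stop("session must be longer than twice the maximum lag")
  res <- lag_pearson_all(regressor$values, dff$values, L)
  structure(
    list(lags_s = res$lags / rate, r = res$r, n_used = res$n_used,
         flagged_constant = res$flagged_constant,
         session_id = session_id, is_null = is_null, rate_hz = rate),
    class = "lag_corr_curve"
  )
}

#' @export
print.lag_corr_curve <- function(x, ...) {
  m <- curve_max(x)
  cat(sprintf("<lag_corr_curve>%s %d lags in [%g, %g] s; max r = %.3f at %+.3f s\n",
              if (x$is_null) " (null)" else "", length(x$r),
              min(x$lags_s), max(x$lags_s), m$max_r, m$max_lag_s))
  invisible(x)
}

#' Maximum of a correlation curve
#'
#' Ties are broken toward the smallest absolute lag, then toward the
#' negative lag.
#'
#' @param curve a `lag_corr_curve`.
#' @return list with `max_r` and `max_lag_s`.
#' @export
curve_max <- function(curve) {
  stopifnot(inherits(curve, "lag_corr_curve"))
  ord <- order(-curve$r, abs(curve$lags_s), curve$lags_s)
  i <- ord[1]
  list(max_r = curve$r[i], max_lag_s = curve$lags_s[i])
}

#' Shuffled-null correlation curve
#'
#' Destroys the temporal alignment between licking and calcium while
#' preserving the regressor's event count, value multiset and
#' autocorrelation: the contact regressor is circularly rotated by a
#' uniformly random offset in `[max_lag_s, duration - max_lag_s]`, the lag
#' curve is recomputed, and the `n_shuffles` curves are averaged pointwise.
#'
#' @param dff the dF/F trace.
#' @param contacts an [event_series()] of contact times.
#' @param n_shuffles number of random rotations to average (default 20).
#' @param seed integer seed for the rotation offsets.
#' @param max_lag_s maximum shift in seconds (default 10).
#' @param session_id identifier carried into the curve.
#' @return a `lag_corr_curve` with `is_null = TRUE`.
#' @export
shuffled_null_curve <- function(dff, contacts, n_shuffles = 20, seed = 1L,
                                max_lag_s = 10, session_id = NA_character_) {
  stopifnot(inherits(dff, "ts_signal"))
  rate <- dff$rate_hz
  n <- length(dff$values)
  duration <- (n - 1) / rate
  reg <- contact_regressor(contacts, rate, duration)
  L <- round(max_lag_s * rate)
  lo <- L; hi <- n - 1L - L
  if (hi < lo)
    stop("session too short to draw rotation offsets outside the lag range")
  offsets <- with_seed(as.integer(seed),
                       sample(seq.int(lo, hi), n_shuffles, replace = TRUE))
  acc <- NULL
  for (off in offsets) {
    rot <- c(reg$values[(n - off + 1L):n], reg$values[1L:(n - off)])
    cur <- lag_correlation_curve(dff, ts_signal(rot, rate, dff$t0_s),
                                 max_lag_s, session_id, is_null = TRUE)
    acc <- if (is.null(acc)) cur$r else acc + cur$r
  }
  template <- lag_correlation_curve(dff, reg, max_lag_s, session_id,
                                    is_null = TRUE)
  template$r <- acc / n_shuffles
  template$n_shuffles <- n_shuffles
  template
}

#' Pointwise average of correlation curves
#'
#' @param curves list of `lag_corr_curve`s on identical lag grids.
#' @param is_null flag for the returned mean curve.
#' @param session_id identifier for the returned curve.
#' @return a `lag_corr_curve` whose `r` is the pointwise mean.
#' @export
average_curves <- function(curves, is_null = FALSE, session_id = "mean") {
  stopifnot(length(curves) >= 1)
  lags <- curves[[1]]$lags_s
  for (cv in curves) {
    stopifnot(inherits(cv, "lag_corr_curve"))
    if (length(cv$lags_s) != length(lags) ||
        max(abs(cv$lags_s - lags)) > 1e-12)
      stop("curves must share an identical lag grid")
  }
  out <- curves[[1]]
  out$r <- rowMeans(vapply(curves, `[[`, numeric(length(lags)), "r"))
  out$is_null <- is_null
  out$session_id <- session_id
  out$flagged_constant <- Reduce(`|`, lapply(curves, `[[`, "flagged_constant"))
  out
}

#' Per-animal summary of real and null correlation curves
#'
#' All of an animal's session curves are averaged into a single mean shifted
#' curve, all its null curves into a null mean curve, and the maximum
#' (value, lag) of each mean curve is extracted.
#'
#' @param curves list of per-session `lag_corr_curve`s (real).
#' @param null_curves list of per-session null curves, same lag grid.
#' @param animal_id identifier.
#' @return object of class `animal_corr_summary` with `mean_curve`,
#'   `null_mean_curve`, `max_r`, `max_lag_s`, `null_max_r`,
#'   `null_max_lag_s`, `animal_id`.
#' @export
summarize_animal <- function(curves, null_curves, animal_id = NA_character_) {
  if (!length(curves) || !length(null_curves))
    stop("need at least one real and one null curve")
  mc <- average_curves(curves, is_null = FALSE,
                       session_id = paste0(animal_id, ":mean"))
  nc <- average_curves(null_curves, is_null = TRUE,
                       session_id = paste0(animal_id, ":null_mean"))
  if (length(mc$lags_s) != length(nc$lags_s) ||
      max(abs(mc$lags_s - nc$lags_s)) > 1e-12)
    stop("real and null curves must share an identical lag grid")
  m <- curve_max(mc); nm <- curve_max(nc)
  structure(
    list(animal_id = animal_id, mean_curve = mc, null_mean_curve = nc,
         max_r = m$max_r, max_lag_s = m$max_lag_s,
         null_max_r = nm$max_r, null_max_lag_s = nm$max_lag_s),
    class = "animal_corr_summary"
  )
}

#' @export
print.animal_corr_summary <- function(x, ...) {
  cat(sprintf(
    "<animal_corr_summary> %s: max r = %.3f at %+.3f s (null max %.3f at %+.3f s)\n",
    x$animal_id, x$max_r, x$max_lag_s, x$null_max_r, x$null_max_lag_s))
  invisible(x)
}

#' Paired test of real versus null correlation maxima across animals
#'
#' Two-tailed paired t-test on the per-animal differences
#' `max_r - null_max_r`. A significant positive difference indicates a
#' genuine shifted correlation between licking and calcium activity beyond
#' what temporal shuffling produces.
#'
#' @param summaries list of [summarize_animal()] results (>= 2 animals).
#' @return list with `t_statistic`, `p_value`, `n`, `mean_difference`.
#' @export
paired_shift_test <- function(summaries) {
  if (length(summaries) < 2)
    stop("paired test requires at least 2 animals")
  d <- vapply(summaries, function(s) s$max_r - s$null_max_r, numeric(1))
  if (stats::sd(d) == 0)
    stop("degenerate variance: per-animal differences are identical")
  ht <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(d), mean_difference = mean(d))
}

#' Run the full lick-calcium correlation pipeline on session bundles
#'
#' Convenience wrapper over the whole analysis: per session, photometry
#' preprocessing ([process_photometry()]), contact regressor, real lag
#' curve and (optionally) shuffled null curve; then per-animal summaries
#' and, with at least two animals, the paired test.
#'
#' @param bundles list of `session_bundle`s (each knows its animal id).
#' @param max_lag_s maximum shift (default 10 s).
#' @param n_shuffles shuffles per session for the null (default 20;
#'   0 skips the null and the test).
#' @param seed base seed for the shuffles.
#' @return list with `animal_summaries`, `grand_mean_curve` (across-animal
#'   mean of the per-animal mean curves), `test` (or `NULL`).
#' @export
run_correlation_pipeline <- function(bundles, max_lag_s = 10, n_shuffles = 20,
                                     seed = 1L) {
  by_animal_real <- list(); by_animal_null <- list()
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    ph <- b$photometry
    proc <- process_photometry(ph$f465, ph$f405)
    dur <- ts_duration(proc$dff)
    reg <- contact_regressor(ph$contacts, proc$dff$rate_hz, dur)
    cur <- lag_correlation_curve(proc$dff, reg, max_lag_s, ph$session_id)
    aid <- ph$animal_id
    by_animal_real[[aid]] <- c(by_animal_real[[aid]], list(cur))
    if (n_shuffles > 0) {
      nul <- shuffled_null_curve(proc$dff, ph$contacts, n_shuffles,
                                 seed = as.integer(seed) + i,
                                 max_lag_s = max_lag_s,
                                 session_id = ph$session_id)
      by_animal_null[[aid]] <- c(by_animal_null[[aid]], list(nul))
    }
  }
  summaries <- NULL
  grand <- NULL
  if (n_shuffles > 0) {
    summaries <- lapply(names(by_animal_real), function(a)
      summarize_animal(by_animal_real[[a]], by_animal_null[[a]], a))
    mean_curves <- lapply(summaries, `[[`, "mean_curve")
  } else {
    mean_curves <- lapply(names(by_animal_real), function(a)
      average_curves(by_animal_real[[a]], session_id = paste0(a, ":mean")))
  }
  grand <- average_curves(mean_curves, session_id = "grand_mean")
  test <- if (!is.null(summaries) && length(summaries) >= 2)
    paired_shift_test(summaries) else NULL
  list(animal_summaries = summaries, grand_mean_curve = grand, test = test)
}
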