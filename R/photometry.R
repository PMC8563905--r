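#' Resample a time series onto a uniform grid at a new rate
#'
#' Linear interpolation onto grid points `t0 + k / target_rate_hz`,
#' `k = 0, ..., floor(duration * target_rate_hz)`, where `duration` is the
#' span from first to last sample. Used to bring the demodulated photometry
#' channels onto the 120 Hz grid of the video recordings before any further
#' processing.
#'
#' @param x a [ts_signal()].
#' @param target_rate_hz new sampling rate in Hz, strictly positive.
#' @return a [ts_signal()] at `target_rate_hz` with the same `t0_s`.
#' @export
resample_ts <- function(x, target_rate_hz) {
  stopifnot(inherits(x, "ts_signal"))
  if (length(x$values) < 1L) stop("cannot resample an empty series")
  if (!is.numeric(target_rate_hz) || length(target_rate_hz) != 1L ||
      target_rate_hz <= 0)
    stop("target rate must be a single positive number")
  dur <- ts_duration(x)
  n_out <- floor(dur * target_rate_hz + 1e-9) + 1L
  t_out <- x$t0_s + (seq_len(n_out) - 1) / target_rate_hz
  if (length(x$values) == 1L) {
    v <- rep(x$values, n_out)
  } else {
    v <- stats::approx(ts_time(x), x$values, xout = t_out, rule = 2)$y
  }
  ts_signal(v, target_rate_hz, x$t0_s)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass at `cutoff_hz` forward and
#' backward (zero phase, effective magnitude response squared). The series is
#' extended at both ends by odd reflection over one settling length before
#' filtering and trimmed afterwards, so output length equals input length.
#' The first and last `edge_s` seconds remain edge-affected and are flagged
#' in the returned attributes.
#'
#' @param x a [ts_signal()].
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order filter order of a single pass (default 2).
#' @return a filtered [ts_signal()]; attribute `"edge_affected_s"` records the
#'   span near each end where transients may persist.
#' @export
lowpass_ts <- function(x, cutoff_hz = 20, order = 2L) {
  stopifnot(inherits(x, "ts_signal"))
  nyq <- x$rate_hz / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyq))
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  v <- x$values
  n <- length(v)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # settling length: a few time constants of the cutoff period
  np <- min(n - 1L, as.integer(ceiling(3 * x$rate_hz / cutoff_hz) * order))
  if (np >= 1L) {
    head_ext <- 2 * v[1] - v[seq(np + 1L, 2L)]
    tail_ext <- 2 * v[n] - v[seq(n - 1L, n - np)]
    vp <- c(head_ext, v, tail_ext)
  } else {
    vp <- v
  }
  fwd <- signal::filter(bf, vp)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  out <- bwd[np + seq_len(n)]
  res <- ts_signal(as.numeric(out), x$rate_hz, x$t0_s)
  attr(res, "edge_affected_s") <- 0.5
  res
}

#' Fit the calcium-independent baseline from the isosbestic channel
#'
#' The fitted baseline F0 is an affine (least-squares) map of the 405 nm
#' isosbestic signal onto the 465 nm calcium-dependent signal:
#' `F0 = intercept + slope * F405`. Because bleaching and motion affect both
#' excitation wavelengths while calcium transients affect only 465 nm, F0
#' captures the shared artifacts and `(F - F0)/F0` removes them.
#'
#' @param f465 calcium-dependent channel, a [ts_signal()].
#' @param c405 isosbestic control channel on the same grid.
#' @param method `"ols"` (default): ordinary least squares of F465 on F405;
#'   `"scale"`: F0 = F405 rescaled by the ratio of channel means (no
#'   intercept). Both readings of a least-squares mean fit are exposed; OLS
#'   is the default.
#' @return an object of class `baseline_fit` with elements `slope`,
#'   `intercept`, `f0` (a [ts_signal()]), `rss` and `method`.
#' @export
fit_isosbestic_baseline <- function(f465, c405, method = c("ols", "scale")) {
  method <- match.arg(method)
  stopifnot(inherits(f465, "ts_signal"), inherits(c405, "ts_signal"))
  if (!same_grid(f465, c405))
    stop("f465 and c405 must share the same sampling grid")
  if (length(f465$values) < 3L)
    stop("need at least 3 samples to fit a baseline")
  y <- f465$values
  x <- c405$values
  if (stats::sd(x) <= 1e-12 * max(abs(x), 1))
    stop("isosbestic channel is constant: baseline regression is degenerate")
  if (method == "ols") {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    f0v <- intercept + slope * x
  } else {
    slope <- mean(y) / mean(x)
    intercept <- 0
    f0v <- slope * x
  }
  rss <- sum((y - f0v)^2)
  structure(
    list(slope = slope, intercept = intercept,
         f0 = ts_signal(f0v, f465$rate_hz, f465$t0_s),
         rss = rss, method = method),
    class = "baseline_fit"
  )
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> [%s] F0 = %.4g + %.4g * F405, rss = %.4g\n",
              x$method, x$intercept, x$slope, x$rss))
  invisible(x)
}

#' Fractional fluorescence change dF/F
#'
#' Elementwise `(F - F0) / F0` with the fitted baseline. Every baseline
#' sample must be strictly positive; a non-positive F0 would make the ratio
#' meaningless and signals an upstream problem (e.g. a failed fit).
#'
#' @param f465 the (resampled, filtered) 465 nm channel, a [ts_signal()].
#' @param fit a `baseline_fit` from [fit_isosbestic_baseline()].
#' @return a [ts_signal()] of dimensionless dF/F samples, with a
#'   `"provenance"` attribute recording the fit coefficients.
#' @export
compute_dff <- function(f465, fit) {
  stopifnot(inherits(f465, "ts_signal"), inherits(fit, "baseline_fit"))
  f0 <- fit$f0$values
  if (!same_grid(f465, fit$f0))
    stop("f465 and the fitted baseline must share the same grid")
  bad <- which(f0 <= 0)
  if (length(bad))
    stop(sprintf("baseline F0 is non-positive at sample %d (value %g)",
                 bad[1], f0[bad[1]]))
  dff <- ts_signal((f465$values - f0) / f0, f465$rate_hz, f465$t0_s)
  attr(dff, "provenance") <- list(slope = fit$slope, intercept = fit$intercept,
                                  method = fit$method)
  dff
}

#' Full photometry preprocessing pipeline
#'
#' Fixed stage order: resample both channels to the analysis rate, zero-phase
#' low-pass both, fit the isosbestic baseline, compute dF/F. The order and
#' all parameters are recorded in the returned provenance so a processed
#' trace can always be traced back to its settings.
#'
#' @param f465,f405 raw demodulated channels as [ts_signal()]s on a common
#'   grid.
#' @param target_rate_hz analysis rate (default 120 Hz, the video rate).
#' @param cutoff_hz low-pass cutoff (default 20 Hz).
#' @param order Butterworth order per pass (default 2).
#' @param method baseline fit method, see [fit_isosbestic_baseline()].
#' @return list with elements `dff` (a [ts_signal()]), `fit` (the
#'   `baseline_fit`) and `provenance` (named list of all parameters plus the
#'   stage order and the edge-affected span).
#' @export
process_photometry <- function(f465, f405, target_rate_hz = 120,
                               cutoff_hz = 20, order = 2L,
                               method = c("ols", "scale")) {
  method <- match.arg(method)
  r465 <- resample_ts(f465, target_rate_hz)
  r405 <- resample_ts(f405, target_rate_hz)
  l465 <- lowpass_ts(r465, cutoff_hz, order)
  l405 <- lowpass_ts(r405, cutoff_hz, order)
  fit <- fit_isosbestic_baseline(l465, l405, method = method)
  dff <- compute_dff(l465, fit)
  prov <- list(
    stages = c("resample", "lowpass", "fit_isosbestic_baseline", "compute_dff"),
    target_rate_hz = target_rate_hz, cutoff_hz = cutoff_hz, order = order,
    method = method, slope = fit$slope, intercept = fit$intercept,
    edge_affected_s = attr(l465, "edge_affected_s")
  )
  attr(dff, "provenance") <- prov
  list(dff = dff, fit = fit, provenance = prov)
}
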