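#' Uniformly sampled time series
#'
#' `ts_signal` is the backbone container for photometry traces, kinematic
#' channels and regressors: a numeric vector sampled at a fixed rate with a
#' known start time. All pipeline stages consume and return this class so
#' that sampling-grid bookkeeping cannot silently drift.
#'
#' @param values numeric vector of samples (arbitrary units).
#' @param rate_hz sampling rate in Hz, strictly positive.
#' @param t0_s time of the first sample in seconds (default 0).
#' @return an object of class `ts_signal`.
#' @export
ts_signal <- function(values, rate_hz, t0_s = 0) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("'rate_hz' must be a single positive number")
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  structure(
    list(values = as.numeric(values), rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s)),
    class = "ts_signal"
  )
}

#' Sample times of a time series
#'
#' @param x a [ts_signal()].
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "ts_signal"))
  x$t0_s + (seq_along(x$values) - 1) / x$rate_hz
}

#' Duration spanned by a time series (first to last sample)
#' @param x a [ts_signal()].
#' @return duration in seconds.
#' @export
ts_duration <- function(x) (length(x$values) - 1) / x$rate_hz

#' @export
print.ts_signal <- function(x, ...) {
  cat(sprintf("<ts_signal> %d samples @ %g Hz, t0 = %g s, range [%.4g, %.4g]\n",
              length(x$values), x$rate_hz, x$t0_s,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.ts_signal <- function(x) length(x$values)

# internal: check two series share the same sampling grid
same_grid <- function(a, b) {
  isTRUE(all.equal(a$rate_hz, b$rate_hz)) &&
    isTRUE(all.equal(a$t0_s, b$t0_s)) &&
    length(a$values) == length(b$values)
}

#' Sorted event times (lick onsets, lick-port contacts, stimulus onsets)
#'
#' @param times_s numeric vector of event times in seconds; must be strictly
#'   increasing. May be empty.
#' @param kind one of `"lick_onset"`, `"contact"`, `"stim_onset"`.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times_s = numeric(0),
                         kind = c("contact", "lick_onset", "stim_onset")) {
  kind <- match.arg(kind)
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1 && any(diff(times_s) <= 0))
    stop("event times must be strictly increasing")
  if (any(!is.finite(times_s)))
    stop("event times must be finite")
  structure(list(times_s = times_s, kind = kind), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s events", length(x$times_s), x$kind))
  if (length(x$times_s))
    cat(sprintf(" in [%.3f, %.3f] s", min(x$times_s), max(x$times_s)))
  cat("\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times_s)

#' Per-frame pose-estimation track for one body part
#'
#' Holds x, y positions (pixels, or mm after calibration) and the tracker's
#' per-frame likelihood at the video rate.
#'
#' @param x,y numeric positional channels, equal length.
#' @param likelihood per-frame probability in `[0, 1]`, same length.
#' @param rate_hz frame rate in Hz (120 for the recordings emulated here).
#' @param body_part label, e.g. `"jaw"` or `"tongue"`.
#' @param units `"px"` or `"mm"`.
#' @param t0_s time of the first frame.
#' @return an object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood, rate_hz, body_part = "jaw",
                       units = c("px", "mm"), t0_s = 0) {
  units <- match.arg(units)
  n <- length(y)
  if (length(x) != n || length(likelihood) != n)
    stop("x, y and likelihood must have equal length")
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE))
    stop("likelihood must lie in [0, 1]")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         likelihood = as.numeric(likelihood),
         rate_hz = as.numeric(rate_hz), body_part = body_part,
         units = units, t0_s = as.numeric(t0_s)),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %s: %d frames @ %g Hz [%s]\n",
              x$body_part, length(x$y), x$rate_hz, x$units))
  invisible(x)
}

#' Frame times of a pose track
#' @param track a [pose_track()].
#' @return numeric vector of frame times in seconds.
#' @export
track_time <- function(track) {
  track$t0_s + (seq_along(track$y) - 1) / track$rate_hz
}

# internal: deterministic substream seed (< 2^31) from a session seed and a
# stream name, so toggling one artifact never perturbs the others
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer((abs(as.numeric(seed)) %% 65521) * 32749 + h * 101 + 7)
}

# internal: evaluate expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
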