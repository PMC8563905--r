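#' Calibrate a pose track to millimetres and smooth it
#'
#' Pixel coordinates are converted to mm using a 5 mm scale bar imaged at
#' `scale_bar_px` pixels, then x and y are smoothed with a Savitzky-Golay
#' filter (likelihood is left untouched). Savitzky-Golay reproduces
#' polynomials up to its order exactly, so genuine lick-cycle waveforms are
#' preserved while frame-to-frame tracker jitter is attenuated.
#'
#' @param track a [pose_track()] in pixel units.
#' @param scale_bar_px pixels spanned by the 5 mm scale bar.
#' @param window odd smoothing window length in frames (default 11).
#' @param poly_order polynomial order (default 3; must be < window).
#' @return a calibrated, smoothed [pose_track()] in mm.
#' @export
calibrate_and_smooth <- function(track, scale_bar_px, window = 11L,
                                 poly_order = 3L) {
  stopifnot(inherits(track, "pose_track"))
  if (scale_bar_px <= 0) stop("scale_bar_px must be positive")
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= poly_order) stop("window must exceed poly_order")
  if (window >= length(track$y)) stop("window must be shorter than the track")
  mm_per_px <- 5 / scale_bar_px
  sm <- function(v) signal::sgolayfilt(v * mm_per_px, p = poly_order, n = window)
  pose_track(sm(track$x), sm(track$y), track$likelihood, track$rate_hz,
             track$body_part, units = "mm", t0_s = track$t0_s)
}

#' Subtract a baseline position from a pose track
#'
#' Two baseline modes mirror the two experimental contexts. `"prestim"`
#' (optogenetics): for each stimulus the baseline is the mean y over
#' 50-100 ms before its onset, and is subtracted piecewise from that
#' stimulus until the next. `"quiescent"` (photometry): the baseline is the
#' mean y over quiescent stretches - runs where the frame-to-frame speed
#' stays below `motion_thresh` for at least `min_quiet_s` seconds (only the
#' first `max_quiet_s` seconds of each run contribute) - subtracted from
#' the whole track.
#'
#' @param track a calibrated [pose_track()] (mm).
#' @param mode `"prestim"` or `"quiescent"`.
#' @param stim_onsets an [event_series()] of stimulus onsets (prestim mode).
#' @param motion_thresh quiescence speed threshold in mm per frame
#'   (default 0.05).
#' @param min_quiet_s,max_quiet_s bounds on quiescent-period length used for
#'   the baseline (defaults 1 and 3 s).
#' @return a baseline-subtracted [pose_track()]; attribute `"baseline_mm"`
#'   holds the value(s) subtracted.
#' @export
normalize_baseline <- function(track, mode = c("prestim", "quiescent"),
                               stim_onsets = NULL, motion_thresh = 0.05,
                               min_quiet_s = 1, max_quiet_s = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "pose_track"))
  t <- track_time(track)
  y <- track$y
  if (mode == "prestim") {
    if (is.null(stim_onsets) || !length(stim_onsets$times_s))
      stop("prestim mode requires stimulus onsets")
    ons <- stim_onsets$times_s
    bases <- vapply(ons, function(o) {
      sel <- t >= o - 0.100 & t <= o - 0.050
      if (!any(sel)) stop(sprintf(
        "no frames in the 50-100 ms pre-stimulus window of onset %.3f s", o))
      mean(y[sel])
    }, numeric(1))
    # piecewise: frames before the second onset use baseline 1, etc.
    seg <- findInterval(t, ons[-1]) + 1L
    ynorm <- y - bases[seg]
    out <- pose_track(track$x, ynorm, track$likelihood, track$rate_hz,
                      track$body_part, track$units, track$t0_s)
    attr(out, "baseline_mm") <- bases
    return(out)
  }
  # quiescent mode
  speed <- abs(diff(y))
  quiet <- c(speed < motion_thresh, FALSE)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_frames <- ceiling(min_quiet_s * track$rate_hz)
  max_frames <- floor(max_quiet_s * track$rate_hz)
  sel_idx <- integer(0)
  for (k in which(r$values & r$lengths >= min_frames)) {
    idx <- starts[k]:min(ends[k], starts[k] + max_frames - 1L)
    sel_idx <- c(sel_idx, idx)
  }
  if (!length(sel_idx))
    stop("no quiescent period of at least ", min_quiet_s,
         " s found; consider reviewing motion_thresh")
  base <- mean(y[sel_idx])
  out <- pose_track(track$x, y - base, track$likelihood, track$rate_hz,
                    track$body_part, track$units, track$t0_s)
  attr(out, "baseline_mm") <- base
  out
}

#' Gate low-likelihood tongue estimates to a baseline position
#'
#' The tongue is only visible while protruded, so tracker estimates at
#' frames with likelihood below `threshold` (default 5%) are aberrant and
#' are replaced by the resting baseline. If `baseline` is not supplied it is
#' derived empirically as the y position on the last frame preceding the
#' first detected protrusion. If no frame ever reaches the threshold the
#' whole trace is set to the median position and the returned
#' `"tongue_never_detected"` attribute is `TRUE`.
#'
#' @param track a tongue [pose_track()].
#' @param threshold likelihood cutoff (default 0.05).
#' @param baseline resting y position (same units as the track); derived if
#'   `NULL`.
#' @return a gated [pose_track()] with attributes `"gate_mask"` (logical,
#'   `TRUE` where replaced), `"baseline"` and `"tongue_never_detected"`.
#' @export
gate_tongue <- function(track, threshold = 0.05, baseline = NULL) {
  stopifnot(inherits(track, "pose_track"))
  low <- track$likelihood < threshold
  never <- all(low)
  if (is.null(baseline)) {
    if (never) {
      baseline <- stats::median(track$y)
    } else {
      first_prot <- which(!low)[1]
      baseline <- if (first_prot > 1) track$y[first_prot - 1L]
                  else track$y[first_prot]
    }
  }
  y <- track$y
  y[low] <- baseline
  out <- pose_track(track$x, y, track$likelihood, track$rate_hz,
                    track$body_part, track$units, track$t0_s)
  attr(out, "gate_mask") <- low
  attr(out, "baseline") <- baseline
  attr(out, "tongue_never_detected") <- never
  out
}

#' Detect lick onsets from a jaw (or tongue) track
#'
#' Lick onsets are the peaks of the first derivative of the position within
#' each lick: the instants of fastest movement in the opening direction.
#' The track's polarity is normalized first (the more-deflecting direction
#' relative to the median is taken as positive), then local maxima of the
#' first difference are kept if they exceed `prominence_mult` times the
#' median absolute first difference, with at most one onset per
#' `refractory_s` refractory period.
#'
#' @param track a calibrated, baseline-normalized [pose_track()].
#' @param prominence_mult multiplier of the median absolute first difference
#'   used as the peak threshold (default 3).
#' @param refractory_s minimum spacing between onsets in seconds
#'   (default 0.05).
#' @return an [event_series()] of kind `"lick_onset"` (possibly empty).
#' @export
detect_lick_onsets <- function(track, prominence_mult = 3, refractory_s = 0.05) {
  stopifnot(inherits(track, "pose_track"))
  y <- track$y
  med <- stats::median(y)
  if (abs(min(y) - med) > abs(max(y) - med)) y <- -y
  d <- diff(y)
  if (all(d == 0)) return(event_series(numeric(0), "lick_onset"))
  # floor at 5% of the strongest movement so numerical ripple on otherwise
  # still stretches never registers as an onset
  thr <- max(prominence_mult * stats::median(abs(d)), 0.05 * max(abs(d)),
             .Machine$double.eps)
  mind <- max(1L, round(refractory_s * track$rate_hz))
  pk <- pracma::findpeaks(d, minpeakheight = thr, minpeakdistance = mind)
  if (is.null(pk)) return(event_series(numeric(0), "lick_onset"))
  idx <- sort(pk[, 2])
  # derivative sample i sits between frames i and i+1
  times <- track$t0_s + (idx - 0.5) / track$rate_hz
  event_series(times, "lick_onset")
}

#' A detected lick bout
#'
#' @param onsets numeric vector of onset times (>= 2, sorted).
#' @return object of class `lick_bout` with fields `onsets`, `n`, `span_s`.
#' @export
lick_bout <- function(onsets) {
  if (length(onsets) < 2) stop("a bout requires at least 2 onsets")
  structure(list(onsets = as.numeric(onsets), n = length(onsets),
                 span_s = max(onsets) - min(onsets)),
            class = "lick_bout")
}

#' @export
print.lick_bout <- function(x, ...) {
  cat(sprintf("<lick_bout> %d licks over %.3f s (start %.3f s)\n",
              x$n, x$span_s, min(x$onsets)))
  invisible(x)
}

#' Segment lick onsets into bouts and unitary licking events
#'
#' Maximal runs of onsets whose consecutive inter-lick intervals are all
#' below `max_ili_s` form bouts (at least 2 licks); isolated onsets are
#' returned separately as unitary licking events.
#'
#' @param onsets an [event_series()] of lick onsets.
#' @param max_ili_s bout-splitting gap in seconds (default 0.5, i.e. more
#'   than three missed cycles at the 7 Hz lapping rate).
#' @return list with elements `bouts` (list of [lick_bout()]) and `unitary`
#'   (an [event_series()]).
#' @export
segment_bouts <- function(onsets, max_ili_s = 0.5) {
  stopifnot(inherits(onsets, "event_series"))
  tt <- onsets$times_s
  if (!length(tt))
    return(list(bouts = list(), unitary = event_series(numeric(0), "lick_onset")))
  grp <- cumsum(c(TRUE, diff(tt) >= max_ili_s))
  runs <- split(tt, grp)
  bouts <- lapply(Filter(function(r) length(r) >= 2, runs), lick_bout)
  names(bouts) <- NULL
  singles <- unlist(Filter(function(r) length(r) < 2, runs), use.names = FALSE)
  if (is.null(singles)) singles <- numeric(0)
  list(bouts = bouts, unitary = event_series(singles, "lick_onset"))
}

#' Lick frequency of a bout
#'
#' Two estimators are exposed. `"interval"` (default) returns
#' `(n - 1) / span`, the reciprocal of the mean inter-lick interval: on
#' perfectly periodic licking it returns the generative rate exactly.
#' `"count_over_span"` returns `n / span`, the number of lick events divided
#' by the time from first to last lick; it overestimates a periodic rate by
#' the factor `n / (n - 1)` and is kept selectable for comparability with
#' analyses that use that convention.
#'
#' @param bout a [lick_bout()].
#' @param estimator `"interval"` or `"count_over_span"`.
#' @return frequency in Hz.
#' @export
lick_frequency <- function(bout, estimator = c("interval", "count_over_span")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(bout, "lick_bout"))
  if (bout$n < 2) stop("frequency is undefined for fewer than 2 licks")
  if (bout$span_s <= 0) stop("bout span must be positive")
  if (estimator == "interval") (bout$n - 1) / bout$span_s
  else bout$n / bout$span_s
}
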