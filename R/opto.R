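#' Optogenetic stimulation train
#'
#' @param onsets_s sorted pulse onset times in seconds.
#' @param width_s pulse width in seconds.
#' @param rate_hz train rate in Hz; 0 denotes single-pulse (non-train)
#'   protocols.
#' @return object of class `stim_train` with derived `duty` (= width * rate
#'   for trains, `NA` for single pulses).
#' @export
stim_train <- function(onsets_s, width_s, rate_hz = 0) {
  onsets_s <- as.numeric(onsets_s)
  if (width_s <= 0) stop("width_s must be positive")
  if (length(onsets_s) > 1 && any(diff(onsets_s) <= 0))
    stop("onsets must be strictly increasing")
  if (rate_hz > 0 && width_s >= 1 / rate_hz)
    stop("pulse width must be shorter than the train period")
  duty <- if (rate_hz > 0) width_s * rate_hz else NA_real_
  structure(list(onsets_s = onsets_s, width_s = width_s,
                 rate_hz = rate_hz, duty = duty),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  if (x$rate_hz > 0)
    cat(sprintf("<stim_train> %d x %g ms pulses at %g Hz (duty %.0f%%)\n",
                length(x$onsets_s), 1000 * x$width_s, x$rate_hz, 100 * x$duty))
  else
    cat(sprintf("<stim_train> %d single pulse(s) of %g ms\n",
                length(x$onsets_s), 1000 * x$width_s))
  invisible(x)
}

#' Build a stimulation protocol
#'
#' For trains (`rate_hz > 0`): pulse onsets at `k / rate_hz` for
#' `k = 0, ..., ceiling(train_duration_s * rate_hz) - 1`, with duty cycle
#' stored as `width_s * rate_hz`. For `rate_hz = 0`: a single continuous
#' pulse of `pulse_width_s` at time 0. The protocol set emulated here uses
#' single pulses of 50-1000 ms and 100 ms-pulse trains at 4-7 Hz; note that
#' duty is always derived from the pulse width, which is treated as
#' authoritative.
#'
#' @param pulse_width_s pulse width in seconds.
#' @param rate_hz train rate in Hz (0 for a single pulse).
#' @param train_duration_s train span in seconds (ignored for single pulses).
#' @return a [stim_train()].
#' @export
build_stim_protocol <- function(pulse_width_s, rate_hz = 0,
                                train_duration_s = NULL) {
  if (pulse_width_s <= 0) stop("pulse width must be positive")
  if (rate_hz == 0)
    return(stim_train(0, pulse_width_s, 0))
  if (pulse_width_s >= 1 / rate_hz)
    stop(sprintf("pulse width (%g s) must be below the period (%g s)",
                 pulse_width_s, 1 / rate_hz))
  if (is.null(train_duration_s) || train_duration_s <= 0)
    stop("train_duration_s required for rate_hz > 0")
  k <- seq_len(ceiling(train_duration_s * rate_hz)) - 1L
  stim_train(k / rate_hz, pulse_width_s, rate_hz)
}

#' Extract baseline-normalized trials around stimulation
#'
#' For single-pulse protocols (`rate_hz = 0`) each onset yields one trial
#' window `[-pre_s, +post_s]` around it; for trains the whole train is one
#' stimulation epoch and yields a single trial spanning it (a 4-7 Hz train
#' is one continuous stimulus as far as the evoked movement is concerned).
#' Each trial's y trace is normalized to its mean over 50-100 ms before the
#' (first) pulse onset. Trials without enough margin inside the recording
#' are dropped and logged; for single pulses, a window overlapping the next
#' onset is truncated there and flagged.
#'
#' @param track a calibrated [pose_track()] (mm).
#' @param stim a [stim_train()].
#' @param pre_s,post_s window margins around the stimulus (defaults 0.5 and
#'   1.5 s).
#' @return list of trials; each trial is a list with `t_s` (time relative to
#'   stimulus onset), `y` (baseline-normalized), `rate_hz`,
#'   `stim_window_s` (pulse width, or train span for trains), `truncated`.
#'   Attribute `"dropped"` lists onsets without margin.
#' @export
extract_trials <- function(track, stim, pre_s = 0.5, post_s = 1.5) {
  stopifnot(inherits(track, "pose_track"), inherits(stim, "stim_train"))
  t <- track_time(track)
  t_end <- t[length(t)]
  if (stim$rate_hz > 0) {
    starts <- stim$onsets_s[1]
    windows <- stim$onsets_s[length(stim$onsets_s)] + stim$width_s - starts
  } else {
    starts <- stim$onsets_s
    windows <- rep(stim$width_s, length(starts))
  }
  trials <- list(); dropped <- numeric(0)
  for (i in seq_along(starts)) {
    on <- starts[i]
    hi <- if (stim$rate_hz > 0) on + windows[i] + post_s else on + post_s
    truncated <- FALSE
    if (stim$rate_hz == 0 && i < length(starts) && starts[i + 1] < hi) {
      hi <- starts[i + 1]
      truncated <- TRUE
    }
    if (on - pre_s < t[1] - 1e-9 || hi > t_end + 1e-9) {
      dropped <- c(dropped, on)
      next
    }
    sel <- t >= on - pre_s - 1e-9 & t <= hi + 1e-9
    bsel <- t >= on - 0.100 - 1e-9 & t <= on - 0.050 + 1e-9
    if (!any(bsel)) { dropped <- c(dropped, on); next }
    trials[[length(trials) + 1L]] <- list(
      t_s = t[sel] - on, y = track$y[sel] - mean(track$y[bsel]),
      rate_hz = track$rate_hz, stim_window_s = windows[i],
      onset_s = on, truncated = truncated)
  }
  if (!length(trials))
    stop("no usable trials: every stimulus lacked margin in the recording")
  attr(trials, "dropped") <- dropped
  trials
}

#' Classify an optogenetically evoked jaw/tongue response
#'
#' Distinguishes the three phenotypes seen under increasing stimulus
#' duration: a `transient` deflection tracking a short pulse, a `sustained`
#' opening held for the whole stimulus, and `rhythmic` re-licking in which
#' a long stationary stimulus triggers repeated movement cycles at the
#' lapping rate. Peaks of the displacement during the stimulus window are
#' detected (half-maximum height threshold, 50 ms refractory - the
#' amplitude-invariant analogue of the lick-onset prominence rule). The
#' class is `rhythmic` if there are at least 3 peaks whose cycle periods
#' have a coefficient of variation below 0.5, `sustained` if the
#' displacement stays beyond half-maximum for over 80% of the window with
#' fewer than 3 peaks, and `transient` otherwise. All thresholds are
#' relative, so the classification is invariant to amplitude scaling.
#'
#' @param trial one trial from [extract_trials()].
#' @param stim_window_s stimulus window length in seconds (defaults to the
#'   trial's own).
#' @param refractory_s minimum peak spacing (default 0.05 s).
#' @return object of class `evoked_response`: list with `class`,
#'   `onset_latency_s`, `amplitude_mm`, `cycle_count` and (rhythmic only)
#'   `frequency_hz` = (peaks - 1) / (time from first to last peak).
#' @export
classify_evoked_response <- function(trial, stim_window_s = trial$stim_window_s,
                                     refractory_s = 0.05) {
  stopifnot(is.list(trial), !is.null(trial$t_s), !is.null(trial$y))
  if (stim_window_s <= 0) stop("stim_window_s must be positive")
  if (stim_window_s > max(trial$t_s) + 1e-9)
    stop("stimulus window extends beyond the trial")
  win <- trial$t_s >= 0 & trial$t_s <= stim_window_s + 1e-9
  y <- trial$y[win]
  tw <- trial$t_s[win]
  if (abs(min(y)) > abs(max(y))) y <- -y
  amp <- max(y)
  if (amp <= 0) {
    return(structure(list(class = "transient", onset_latency_s = NA_real_,
                          amplitude_mm = 0, cycle_count = 0L,
                          frequency_hz = NA_real_),
                     class = "evoked_response"))
  }
  half <- amp / 2
  occupancy <- mean(y >= half)
  mind <- max(1L, round(refractory_s * trial$rate_hz))
  pk <- pracma::findpeaks(y, minpeakheight = half, minpeakdistance = mind)
  npk <- if (is.null(pk)) 0L else nrow(pk)
  peak_t <- if (npk) sort(tw[pk[, 2]]) else numeric(0)
  cv <- if (npk >= 3) {
    per <- diff(peak_t)
    stats::sd(per) / mean(per)
  } else NA_real_
  cls <- if (npk >= 3 && isTRUE(cv < 0.5)) "rhythmic"
         else if (occupancy > 0.8 && npk < 3) "sustained"
         else "transient"
  freq <- if (cls == "rhythmic")
    (npk - 1) / (peak_t[npk] - peak_t[1]) else NA_real_
  latency <- tw[which(y >= half)[1]]
  structure(
    list(class = cls, onset_latency_s = latency, amplitude_mm = amp,
         cycle_count = npk, frequency_hz = freq,
         period_cv = cv, halfmax_occupancy = occupancy),
    class = "evoked_response"
  )
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> %s: %d peak(s), amplitude %.2f mm%s\n",
              x$class, x$cycle_count, x$amplitude_mm,
              if (!is.na(x$frequency_hz))
                sprintf(", %.2f Hz", x$frequency_hz) else ""))
  invisible(x)
}

#' Synthetic evoked jaw trace for a stimulation protocol
#'
#' Builds a noise-free jaw trial for testing and demonstration. Three
#' response modes mirror the evoked phenotypes: `"follow"` places one
#' raised-cosine deflection per pulse (1:1 train following); `"sustained"`
#' holds a step displacement for the whole stimulus; `"rhythmic"` fills the
#' stimulus window with raised-cosine cycles at `cycle_rate_hz` regardless
#' of the pulse pattern (the long-pulse re-licking phenotype).
#'
#' @param stim a [stim_train()].
#' @param mode `"follow"`, `"sustained"` or `"rhythmic"`.
#' @param rate_hz video rate (default 120).
#' @param pre_s,post_s margins around the stimulus (defaults 0.5, 1.5 s).
#' @param amplitude_mm deflection amplitude (default 2).
#' @param cycle_rate_hz rhythmic cycle rate (default 7).
#' @param cycle_fraction deflection length as a fraction of the pulse period
#'   in follow mode (default 0.8).
#' @return a [pose_track()] in mm whose time origin places the first pulse
#'   at `pre_s` seconds into the track.
#' @export
synth_evoked_track <- function(stim, mode = c("follow", "sustained", "rhythmic"),
                               rate_hz = 120, pre_s = 0.5, post_s = 1.5,
                               amplitude_mm = 2, cycle_rate_hz = 7,
                               cycle_fraction = 0.8) {
  mode <- match.arg(mode)
  stopifnot(inherits(stim, "stim_train"))
  span <- stim$onsets_s[length(stim$onsets_s)] + stim$width_s
  dur <- pre_s + span + post_s
  n <- ceiling(dur * rate_hz - 1e-9) + 1L
  t <- (seq_len(n) - 1) / rate_hz - pre_s   # t = 0 at first pulse onset
  y <- numeric(n)
  deflect <- function(t0, len) {
    idx <- which(t >= t0 & t < t0 + len)
    ph <- (t[idx] - t0) / len
    y[idx] <<- pmax(y[idx], amplitude_mm * (1 - cos(2 * pi * ph)) / 2)
  }
  if (mode == "follow") {
    period <- if (stim$rate_hz > 0) 1 / stim$rate_hz else stim$width_s * 1.5
    for (on in stim$onsets_s) deflect(on, cycle_fraction * period)
  } else if (mode == "sustained") {
    idx <- which(t >= 0 & t <= span)
    y[idx] <- amplitude_mm
    # soft 25 ms shoulders so the step is trackable
    rise <- which(t >= -0.025 & t < 0)
    y[rise] <- amplitude_mm * (t[rise] + 0.025) / 0.025
    fall <- which(t > span & t <= span + 0.025)
    y[fall] <- amplitude_mm * (span + 0.025 - t[fall]) / 0.025
  } else {
    # one cycle per period for as long as the cycle peak falls inside the
    # stimulus; the last movement may complete after light-off
    period <- 1 / cycle_rate_hz
    ncyc <- max(0L, floor((span - period / 2) / period + 1e-9) + 1L)
    for (k in seq_len(ncyc) - 1L) deflect(k * period, period)
  }
  pose_track(rep(0, n), y, rep(0.99, n), rate_hz, "jaw", "mm", t0_s = -pre_s)
}
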