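#' Calcium indicator impulse kernel
#'
#' The shape convolved with lick-port contacts to build the synthetic
#' calcium trace. Two shapes are supported: a symmetric Gaussian (default;
#' its peak sits exactly at the planted contact-to-peak delay, so the
#' expected correlation-peak lag is known in closed form) and an asymmetric
#' double exponential `exp(-u/tau_decay) - exp(-u/tau_rise)` whose onset is
#' placed at the planted delay (its correlation-peak lag must be measured,
#' not assumed). No kinetic constants for the indicator are published for
#' the preparation emulated here; the defaults are plausible slow-indicator
#' values, not measurements.
#'
#' @param shape `"gaussian"` or `"double_exp"`.
#' @param width_s Gaussian standard deviation in seconds (gaussian shape).
#' @param tau_rise_s,tau_decay_s time constants (double_exp shape).
#' @param amplitude peak amplitude in the same arbitrary units as the
#'   photometry baseline.
#' @return object of class `calcium_kernel`.
#' @export
calcium_kernel <- function(shape = c("gaussian", "double_exp"),
                           width_s = 0.4, tau_rise_s = 0.2, tau_decay_s = 1.0,
                           amplitude = 2) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (shape == "gaussian" && width_s <= 0) stop("width_s must be positive")
  if (shape == "double_exp") {
    if (tau_rise_s <= 0 || tau_decay_s <= 0) stop("time constants must be positive")
    if (tau_rise_s >= tau_decay_s) stop("tau_rise_s must be below tau_decay_s")
  }
  structure(list(shape = shape, width_s = width_s, tau_rise_s = tau_rise_s,
                 tau_decay_s = tau_decay_s, amplitude = amplitude),
            class = "calcium_kernel")
}

# internal: evaluate the kernel at times u relative to its alignment point
# (gaussian: peak at u = 0; double_exp: onset at u = 0), truncated where the
# value falls below 1e-8 of the amplitude
eval_kernel <- function(kernel, u) {
  if (kernel$shape == "gaussian") {
    v <- kernel$amplitude * exp(-u^2 / (2 * kernel$width_s^2))
  } else {
    td <- kernel$tau_decay_s; tr <- kernel$tau_rise_s
    peak_t <- log(td / tr) * tr * td / (td - tr)
    norm <- exp(-peak_t / td) - exp(-peak_t / tr)
    v <- ifelse(u >= 0, (exp(-u / td) - exp(-u / tr)) / norm, 0) * kernel$amplitude
  }
  v[v < 1e-8 * kernel$amplitude] <- 0
  v
}

# internal: kernel support half-width (seconds) beyond which it is truncated
kernel_support_s <- function(kernel) {
  if (kernel$shape == "gaussian") 6.1 * kernel$width_s
  else kernel$tau_decay_s * log(1e8) + 1
}

#' Configuration of the synthetic session generator
#'
#' Bundles every knob of the generator: acquisition rates mirroring the
#' emulated recordings (1200 Hz raw photometry spanning the same raw/video
#' ratio as the hardware, 120 Hz video), the lapping rate (7 Hz, the
#' physiological rate in mice), the bout layout, the contact-to-peak latency
#' of the calcium response (1.2 s by default), the artifact magnitudes and
#' the random seed.
#'
#' @param duration_s session length in seconds (> 0).
#' @param raw_rate_hz raw photometry rate (default 1200; must be a multiple
#'   of `video_rate_hz`).
#' @param video_rate_hz video/analysis rate (default 120).
#' @param lapping_rate_hz lick-cycle rate within bouts (default 7).
#' @param bout_structure data.frame with columns `start_s`, `n_licks`, one
#'   row per bout (a 1-lick bout is a unitary licking event). `NULL` lays
#'   out a deterministic default pattern of bouts and unitary licks for the
#'   session duration.
#' @param contact_to_peak_delay_s latency from lick-port contact to the peak
#'   of the calcium response (default 1.2 s).
#' @param kernel a [calcium_kernel()].
#' @param bleach_tau_s time constant of the shared exponential bleach
#'   (default 600 s; `Inf` disables bleaching).
#' @param motion_amp standard deviation of the shared low-frequency motion
#'   artifact in raw fluorescence units (default 0.5).
#' @param noise_sd per-sample Gaussian noise s.d. per channel (default 0.02).
#' @param scale_bar_px length in pixels of the 5 mm calibration bar in the
#'   video frame (default 100).
#' @param seed integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(duration_s,
                             raw_rate_hz = 1200,
                             video_rate_hz = 120,
                             lapping_rate_hz = 7,
                             bout_structure = NULL,
                             contact_to_peak_delay_s = 1.2,
                             kernel = calcium_kernel(),
                             bleach_tau_s = 600,
                             motion_amp = 0.5,
                             noise_sd = 0.02,
                             scale_bar_px = 100,
                             seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (raw_rate_hz <= 0 || video_rate_hz <= 0 || lapping_rate_hz <= 0)
    stop("all rates must be positive")
  if (abs(raw_rate_hz / video_rate_hz - round(raw_rate_hz / video_rate_hz)) > 1e-9)
    stop("video_rate_hz must divide raw_rate_hz")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (scale_bar_px <= 0) stop("scale_bar_px must be positive")
  if (is.null(bout_structure))
    bout_structure <- default_bout_structure(duration_s, lapping_rate_hz)
  stopifnot(is.data.frame(bout_structure),
            all(c("start_s", "n_licks") %in% names(bout_structure)))
  if (nrow(bout_structure)) {
    ends <- bout_structure$start_s + bout_structure$n_licks / lapping_rate_hz
    if (any(bout_structure$start_s < 0) || any(ends > duration_s))
      stop("bouts must lie within [0, duration_s]")
  }
  structure(
    list(duration_s = duration_s, raw_rate_hz = raw_rate_hz,
         video_rate_hz = video_rate_hz, lapping_rate_hz = lapping_rate_hz,
         bout_structure = bout_structure,
         contact_to_peak_delay_s = contact_to_peak_delay_s,
         kernel = kernel, bleach_tau_s = bleach_tau_s,
         motion_amp = motion_amp, noise_sd = noise_sd,
         scale_bar_px = scale_bar_px, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Deterministic default bout layout for a session
#'
#' A bout roughly every 10 s, with lengths cycling through 8, 12, 5, 1 and
#' 10 licks (the 1-lick entry is a unitary licking event), starting at 5 s.
#' Bouts that would overrun the session (allowing for the calcium response
#' tail) are dropped.
#'
#' @param duration_s session length in seconds.
#' @param lapping_rate_hz lick-cycle rate in Hz.
#' @return data.frame with columns `start_s`, `n_licks`.
#' @export
default_bout_structure <- function(duration_s, lapping_rate_hz = 7) {
  lens <- c(8L, 12L, 5L, 1L, 10L)
  starts <- seq(5, by = 10, length.out = max(0, floor((duration_s - 5) / 10) + 1))
  if (!length(starts) || duration_s < 8)
    return(data.frame(start_s = numeric(0), n_licks = integer(0)))
  n <- lens[(seq_along(starts) - 1L) %% length(lens) + 1L]
  keep <- starts + n / lapping_rate_hz <= duration_s - 3
  data.frame(start_s = starts[keep], n_licks = n[keep])
}

#' Synthetic calcium response to a train of lick-port contacts
#'
#' Superposes one copy of the indicator kernel per contact. For the
#' symmetric Gaussian kernel each copy peaks exactly at
#' `contact time + delay_s`; for the double exponential each copy starts
#' rising at that time. The response is linear in the contact train.
#'
#' @param contacts an [event_series()] of contact times.
#' @param kernel a [calcium_kernel()].
#' @param delay_s contact-to-peak (gaussian) or contact-to-onset
#'   (double_exp) latency in seconds.
#' @param rate_hz output sampling rate.
#' @param duration_s output span in seconds.
#' @return a [ts_signal()] of length `floor(duration_s * rate_hz) + 1`.
#' @export
calcium_response <- function(contacts, kernel, delay_s, rate_hz, duration_s) {
  stopifnot(inherits(contacts, "event_series"), inherits(kernel, "calcium_kernel"))
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  ct <- contacts$times_s
  if (length(ct) && (min(ct) < 0 || max(ct) > duration_s))
    stop("contacts must lie within [0, duration_s]")
  n <- floor(duration_s * rate_hz + 1e-9) + 1L
  out <- numeric(n)
  half <- kernel_support_s(kernel)
  for (c0 in ct) {
    center <- c0 + delay_s
    i0 <- max(1L, floor((center - half) * rate_hz) + 1L)
    i1 <- min(n, ceiling((center + half) * rate_hz) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    u <- (idx - 1) / rate_hz - center
    out[idx] <- out[idx] + eval_kernel(kernel, u)
  }
  ts_signal(out, rate_hz, 0)
}

#' Apply shared bleaching, motion artifact and channel noise
#'
#' Emulates what the isosbestic channel is there to correct: both channels
#' are multiplied by a shared exponential bleach factor, a shared
#' low-frequency motion trace is added with a channel-specific gain
#' proportional to each channel's mean brightness (so the artifact enters
#' both channels in proportion, as a common optical disturbance does), and
#' independent Gaussian noise of s.d. `noise_sd` is added per channel.
#' Randomness is drawn from named substreams (`motion`, `noise465`,
#' `noise405`) derived from `config$seed`, so toggling one artifact never
#' changes the others, and the output is bit-reproducible.
#'
#' @param sig465,sig405 clean channels on a common grid.
#' @param config a [generator_config()].
#' @return list with elements `f465`, `f405` ([ts_signal()]s) and `motion`
#'   (the injected motion trace, for diagnostics).
#' @export
apply_artifacts <- function(sig465, sig405, config) {
  stopifnot(inherits(sig465, "ts_signal"), inherits(sig405, "ts_signal"))
  if (!same_grid(sig465, sig405))
    stop("both channels must share the same sampling grid")
  t <- ts_time(sig465)
  n <- length(t)
  bleach <- if (is.finite(config$bleach_tau_s))
    exp(-t / config$bleach_tau_s) else rep(1, n)
  # shared slow motion: three incommensurate slow sinusoids, random phases
  motion <- numeric(n)
  if (config$motion_amp > 0) {
    ph <- with_seed(substream_seed(config$seed, "motion"), stats::runif(3, 0, 2 * pi))
    freqs <- c(0.11, 0.23, 0.41)
    raw <- rowSums(sapply(seq_along(freqs), function(k)
      sin(2 * pi * freqs[k] * t + ph[k])))
    motion <- raw / stats::sd(raw) * config$motion_amp
  }
  g465 <- 1
  g405 <- mean(sig405$values) / mean(sig465$values)
  n465 <- if (config$noise_sd > 0)
    with_seed(substream_seed(config$seed, "noise465"),
              stats::rnorm(n, 0, config$noise_sd)) else numeric(n)
  n405 <- if (config$noise_sd > 0)
    with_seed(substream_seed(config$seed, "noise405"),
              stats::rnorm(n, 0, config$noise_sd)) else numeric(n)
  f465 <- sig465$values * bleach + g465 * motion + n465
  f405 <- sig405$values * bleach + g405 * motion + n405
  list(f465 = ts_signal(f465, sig465$rate_hz, sig465$t0_s),
       f405 = ts_signal(f405, sig405$rate_hz, sig405$t0_s),
       motion = ts_signal(if (config$motion_amp > 0) motion else numeric(n) + 0,
                          sig465$rate_hz, sig465$t0_s))
}

#' Generate jaw and tongue pose tracks with lick-port contacts
#'
#' Within each bout, each lick cycle (period `1/lapping_rate_hz`) deflects
#' the jaw downward along a raised-cosine waveform and protrudes the tongue
#' during the middle half of the cycle. Tracker likelihood for the tongue is
#' 0.95 during protrusion and 0.02 elsewhere (it is only visible when
#' protruded); the jaw is always visible (likelihood 0.99). One contact
#' event is planted per cycle at maximal protrusion (mid-cycle). The jaw
#' deflection amplitude is chosen so that a 5 mm scale bar of
#' `scale_bar_px` pixels calibrates it to 2 mm.
#'
#' @param config a [generator_config()].
#' @return list with elements `jaw`, `tongue` ([pose_track()]s at the video
#'   rate, pixel units), `contacts` (an [event_series()]) and `truth` (named
#'   list of planted cycle onsets and contact times).
#' @export
generate_pose <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  vr <- config$video_rate_hz
  dur <- config$duration_s
  n <- floor(dur * vr + 1e-9) + 1L
  t <- (seq_len(n) - 1) / vr
  period <- 1 / config$lapping_rate_hz
  jaw_amp_px <- 0.4 * config$scale_bar_px        # 2 mm under 5 mm calibration
  tongue_amp_px <- 0.6 * config$scale_bar_px     # 3 mm protrusion
  jaw_y0 <- 200; tongue_y0 <- 260
  jaw_y <- rep(jaw_y0, n)
  tongue_y <- rep(tongue_y0, n)
  tongue_lik <- rep(0.02, n)
  cycle_onsets <- numeric(0)
  contacts <- numeric(0)
  bs <- config$bout_structure
  for (b in seq_len(nrow(bs))) {
    s <- bs$start_s[b]; nl <- bs$n_licks[b]
    if (s + nl * period > dur + 1e-9)
      stop(sprintf("bout %d extends past the session duration", b))
    for (k in seq_len(nl) - 1L) {
      cs <- s + k * period
      cycle_onsets <- c(cycle_onsets, cs)
      contacts <- c(contacts, cs + period / 2)
      idx <- which(t >= cs & t < cs + period)
      phase <- (t[idx] - cs) / period
      jaw_y[idx] <- jaw_y0 + jaw_amp_px * (1 - cos(2 * pi * phase)) / 2
      prot <- idx[phase >= 0.25 & phase < 0.75]
      pphase <- (t[prot] - cs) / period
      tongue_y[prot] <- tongue_y0 +
        tongue_amp_px * (1 - cos(2 * pi * (pphase - 0.25) / 0.5)) / 2
      tongue_lik[prot] <- 0.95
    }
  }
  truth <- list(cycle_onsets_s = cycle_onsets, contact_times_s = contacts,
                lapping_rate_hz = config$lapping_rate_hz,
                bout_structure = bs)
  list(
    jaw = pose_track(rep(100, n), jaw_y, rep(0.99, n), vr, "jaw", "px"),
    tongue = pose_track(rep(150, n), tongue_y, tongue_lik, vr, "tongue", "px"),
    contacts = event_series(contacts, "contact"),
    truth = truth
  )
}

#' Generate a complete synthetic session
#'
#' Assembles pose tracks, lick-port contacts and two-channel photometry into
#' one bundle with a ground-truth record of every planted parameter. The
#' 465 nm channel is a constant baseline (100 a.u.) plus the calcium
#' response to the contacts; the 405 nm channel is a constant baseline
#' (80 a.u.) with no calcium dependence; both then pass through
#' [apply_artifacts()]. Deterministic given `config` (which includes the
#' seed).
#'
#' @param config a [generator_config()].
#' @param stim optional [stim_train()] to attach (default none).
#' @return object of class `session_bundle` with elements `photometry`
#'   (list: `f465`, `f405`, `contacts`, `session_id`, `animal_id`), `pose`
#'   (list: `jaw`, `tongue`), `stim` (or `NULL`) and `truth`.
#' @param session_id,animal_id identifiers stored with the bundle.
#' @export
generate_session <- function(config, stim = NULL,
                             session_id = "s1", animal_id = "a1") {
  stopifnot(inherits(config, "generator_config"))
  pose <- generate_pose(config)
  cal <- calcium_response(pose$contacts, config$kernel,
                          config$contact_to_peak_delay_s,
                          config$raw_rate_hz, config$duration_s)
  base465 <- 100; base405 <- 80
  clean465 <- ts_signal(base465 + cal$values, config$raw_rate_hz, 0)
  clean405 <- ts_signal(rep(base405, length(cal$values)), config$raw_rate_hz, 0)
  art <- apply_artifacts(clean465, clean405, config)
  truth <- c(pose$truth,
             list(contact_to_peak_delay_s = config$contact_to_peak_delay_s,
                  kernel_shape = config$kernel$shape,
                  noise_sd = config$noise_sd,
                  motion_amp = config$motion_amp,
                  bleach_tau_s = config$bleach_tau_s,
                  seed = config$seed))
  structure(
    list(
      photometry = list(f465 = art$f465, f405 = art$f405,
                        contacts = pose$contacts,
                        session_id = session_id, animal_id = animal_id),
      pose = list(jaw = pose$jaw, tongue = pose$tongue),
      stim = stim,
      truth = truth,
      config = config,
      motion = art$motion
    ),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s/%s: %g s, %d contacts, %s stim\n",
              x$photometry$animal_id, x$photometry$session_id,
              x$config$duration_s, length(x$photometry$contacts),
              if (is.null(x$stim)) "no" else "with"))
  invisible(x)
}
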