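# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# A clean (artifact-free, noise-free) short session config.
clean_config <- function(duration_s = 20,
                         bouts = data.frame(start_s = 5, n_licks = 8),
                         ...) {
  generator_config(duration_s = duration_s, bout_structure = bouts,
                   noise_sd = 0, motion_amp = 0, bleach_tau_s = Inf, ...)
}

# Default-condition session config (noise, motion and bleach at the
# generator defaults) with a chosen seed.
noisy_config <- function(duration_s = 30, seed = 1L, ...) {
  generator_config(duration_s = duration_s, seed = seed, ...)
}

# A session with no calcium coupling at all: zero-amplitude kernel, so dF/F
# contains only residual noise while contacts still occur.
null_coupling_config <- function(duration_s = 30, seed = 1L) {
  generator_config(duration_s = duration_s, seed = seed,
                   kernel = calcium_kernel(amplitude = 0))
}

make_sine_ts <- function(freq_hz, rate_hz, duration_s, amp = 1) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  ts_signal(amp * sin(2 * pi * freq_hz * t), rate_hz, 0)
}
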