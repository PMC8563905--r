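---
title: "Methods: lick-calcium correlation, evoked-movement classification and input mapping"
author: "oromotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lick-calcium correlation, evoked-movement classification and input mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oromotor)
```

# Scope

`oromotor` implements the quantitative pipeline used to relate rodent
licking behaviour to the activity of a medullary premotor population and to
its monosynaptic input map:

1. **Photometry**: two-channel (465 nm calcium-dependent / 405 nm
   isosbestic) bulk-fluorescence preprocessing into a dF/F trace on a
   120 Hz analysis grid.
2. **Kinematics**: post-processing of markerless jaw/tongue pose tracks
   into calibrated trajectories, lick onsets, bouts and frequencies.
3. **Lag correlation**: the session-wise lagged lick-calcium Pearson
   correlation with a circular-shuffle null, per-animal averaging and a
   paired test on curve maxima.
4. **Optogenetics**: stimulus-protocol construction and classification of
   evoked jaw responses as transient, sustained or rhythmic.
5. **Tracing**: per-region quantification of rabies-labeled input neurons.
6. **Synthetic sessions**: a deterministic generator that plants known
   parameters so every stage above has a recoverable target.

# The synthetic-session generator

The generator is first-class, tested code, not a fixture. Its defaults
describe the recording conditions the analysis is designed for:

* video and analysis rate 120 Hz; raw photometry emitted at 1200 Hz
  (the analysis only ever sees the 120 Hz grid, so the raw rate preserves
  the raw-to-video ratio at desk scale rather than the full hardware rate);
* lapping at 7 Hz, the physiological licking rate in mice, organized into
  bouts plus occasional unitary licks (`default_bout_structure()`);
* a calcium response obtained by convolving lick-port contacts with an
  indicator kernel whose peak trails contact by 1.2 s — the latency the
  correlation analysis is expected to recover;
* shared artifacts on both photometry channels: exponential bleaching
  (tau 600 s), a slow motion trace added in proportion to each channel's
  brightness, and independent Gaussian noise (sd 0.02 on a baseline of
  100 a.u.).

No indicator kinetics or noise magnitudes are published for the emulated
preparation; the kernel and artifact defaults are plausible slow-indicator
values chosen once and documented here — they are placeholders, not
measurements. The default kernel is a *symmetric* Gaussian (sd 0.4 s) so
the planted contact-to-peak delay equals the expected correlation-peak lag
exactly; with the asymmetric double-exponential kernel (onset at contact +
delay) the expected peak lag is measured with the brute-force oracle in the
test suite, never assumed.

Randomness is split into named substreams (`motion`, `noise465`,
`noise405`) derived deterministically from the session seed, so disabling
one artifact never changes the draws of another — a property the test
suite verifies by differencing sessions.

The lick-cycle waveform is a raised cosine; the jaw amplitude in pixels is
chosen so the 5 mm scale-bar calibration yields 2 mm deflections (arbitrary
but documented). The tongue is modelled as visible (likelihood 0.95) only
during the middle half of each cycle, with one contact planted at maximal
protrusion, so every contact lies inside a protrusion segment by
construction.

What the generator does *not* emulate: real tracker noise structure
(correlated dropouts, identity swaps), non-stationary lick rates, licking
outside bouts, movement artifacts correlated with behaviour, or hardware
demodulation. Passing tests therefore demonstrate that the pipeline
recovers planted parameters under the stated conditions, not that it is
robust to every failure mode of real recordings.

# Photometry: dF/F with isosbestic correction

The stage order is fixed and recorded in provenance: resample both
channels to 120 Hz (linear interpolation), zero-phase low-pass both
(Butterworth, 20 Hz cutoff, order 2 per pass applied forward-backward),
fit the baseline, compute dF/F. Two sentences of the original protocol
order resampling and filtering oppositely; resample-then-filter is used
here because the 20 Hz low-pass then acts on the grid where it is
specified. Linear interpolation (rather than polyphase decimation) is
acceptable because the subsequent low-pass bounds aliasing at these rates.

The baseline is `F0 = intercept + slope * F405`, the ordinary
least-squares fit of the 465 nm signal on the isosbestic channel, and
`dF/F = (F - F0)/F0`. "Least-squares fit of the 405 signal" could also be
read as rescaling the 405 channel by the ratio of means; both variants are
exposed (`method = "ols"` / `"scale"`), OLS is the default because it is
the standard isosbestic-correction reading and strictly minimizes the
residual. Whenever the 465 channel is an exact affine function of the 405
channel the dF/F is identically zero — the pipeline's null property.

Numerical choices: the filter is applied after odd-reflection padding of
one settling length (about `3 * rate / cutoff` samples per pass order);
the first and last 0.5 s are flagged edge-affected in provenance. A
constant (or numerically constant) isosbestic channel is a degenerate
regressor and raises an error rather than returning a meaningless fit.
dF/F requires strictly positive F0 at every sample and names the first
offending index otherwise.

# Kinematics

* **Calibration**: 5 mm / `scale_bar_px` converts pixels to mm;
  Savitzky-Golay smoothing (window 11 frames, order 3 — unspecified in the
  original protocol, chosen as a standard quarter-lick-cycle window at
  120 Hz) is applied to positions, never to likelihoods.
* **Baseline**: pre-stimulus mode subtracts the mean position 50-100 ms
  before each stimulus; quiescent mode subtracts the mean over still
  stretches (|dy/dt| < 0.05 mm/frame, at least 1 s long, first 3 s of each
  stretch used). The motion threshold is an artifact decision; the error
  raised when no quiescent stretch exists advises reviewing it.
* **Tongue gating**: frames with likelihood < 5% are set to the resting
  baseline, derived (when not supplied) as the position just before the
  first detected protrusion; an entirely gated trace is allowed and
  flagged, not an error. Gating is idempotent.
* **Onsets**: peaks of the first difference of the (polarity-normalized)
  position, thresholded at 3x the median absolute first difference with a
  5%-of-maximum floor and a 50 ms refractory period. The floor prevents
  numerical ripple on motionless stretches from registering as onsets;
  both the multiplier and refractory period are artifact decisions, stated
  here because the original protocol does not specify them.
* **Bouts**: maximal onset runs with gaps below 0.5 s (about three missed
  cycles at 7 Hz; the original criterion is unstated) form bouts of at
  least 2 licks; the rest are unitary licking events.
* **Frequency**: the default estimator is `(n - 1)/span`, the reciprocal
  mean inter-lick interval, because it returns the generative rate exactly
  on periodic input; the literal events-over-span form `n/span`
  overestimates a periodic rate by `n/(n - 1)` and is kept selectable for
  fidelity to analyses that use it.

# Lag correlation

For each session the dF/F trace and the binary contact regressor are
correlated at every integer shift of −10 s … +10 s on the 120 Hz grid
(2401 lags; positive lag = calcium after contact). Overlaps are truncated,
never wrapped, so edge lags use fewer samples; the per-lag counts are
stored. Pearson correlation is used (the correlation type is otherwise
unspecified). The implementation computes all shifts via one FFT
cross-correlation plus cumulative-sum moments (O(n log n)); the test suite
requires equality with a naive one-`cor()`-per-lag oracle to 1e−10, so the
fast path is never trusted on its own. Lags at which either segment is
constant are set to r = 0 and flagged.

The null destroys lick-calcium alignment by circular rotation of the
regressor (uniform offset drawn outside the lag range), which preserves
the event count, value multiset and autocorrelation of the regressor; 20
rotations are averaged per session by default. Whether the original
analysis rotated, permuted event times or shuffled intervals is not
stated; rotation is the most conservative of the three for rhythmic event
trains.

Per animal, session curves and null curves are averaged pointwise and the
maxima of the two mean curves extracted (ties broken toward the smallest
absolute lag, then the negative lag — relevant only for degenerate flat
curves). The maximum of r, not |r|, is used: the real curves peak
positive. Across animals, a two-tailed paired t-test compares real versus
null maxima.

**A caveat on the paired test.** Averaging many shuffled curves shrinks
the null maximum below what a single (equally distributed) curve attains,
so with a many-shuffle null the paired difference is positive even without
any coupling and the test is anti-conservative. This is a property of the
published design, inherited intentionally. The type-I calibration test
therefore uses a single-rotation null, under which real and null maxima
are exchangeable when there is no coupling and the nominal 5% level is
meaningful; users wanting a calibrated test should do the same.

# Optogenetics

Protocols mirror the published set: single pulses of 50-1000 ms and 1 s
trains of 100 ms pulses at 4-7 Hz. Duty cycle is stored as
`width * rate`; the printed duty percentages for the 4/6/7 Hz trains are
inconsistent with 100 ms pulses (they imply 40/60/70%), and the pulse
width is treated as authoritative.

Trial extraction treats a train as one stimulation epoch (one trial
spanning the whole train) and single pulses as one trial each; each trial
is normalized to its 50-100 ms pre-onset baseline. Per-pulse windows for a
7 Hz train would be shorter than one movement cycle, which is why the
train is the unit of analysis.

Classification detects displacement peaks inside the stimulus window
(half-maximum height, 50 ms refractory — the amplitude-invariant analogue
of the onset prominence rule) and applies:

* **rhythmic** — at least 3 peaks whose cycle periods have a coefficient
  of variation below 0.5; frequency = (peaks − 1)/(last − first peak);
* **sustained** — displacement beyond half-maximum for more than 80% of
  the window, with fewer than 3 peaks;
* **transient** — everything else.

The thresholds (3 peaks, CV 0.5, 80% occupancy) are artifact decisions:
the original description of the phenotypes is visual. All criteria are
relative, so classification is invariant to amplitude scaling, which the
test suite checks over four orders of magnitude.

# Tracing quantification

Input (rabies-only) neurons are counted per animal and atlas region;
starter (seed) neurons are excluded from input counts and unknown
acronyms are an error against a user-supplied acronym list (atlas
registration itself is upstream and out of scope). "Normalized and
pooled" is read as: per-animal percentages of that animal's input total,
pooled as the unweighted mean across animals with the SEM across animals,
so animals with different labeling totals weigh equally; a pooled-count
mode is selectable for comparison. The 0.3% cutoff affects display
flagging only and never alters totals. Seeding efficiency is the mean of
per-animal input/starter ratios — not the ratio of pooled counts, which
differs whenever totals differ between animals. SEM over a single animal
is reported as absent, not zero.

# Problem sizes and reproducibility

The validation suite runs the full correlation pipeline on 4 synthetic
animals x 4 sessions of 120 s, oracle-equivalence checks on 30 s
sessions, and 200 null replicates of 4 x 30 s sessions for the type-I
calibration — sizes at which every stochastic property is stable across
seeds while the whole suite completes in about a minute. All randomness
flows from explicit integer seeds; sessions are bit-reproducible given
(config, seed), and `write_session()` serializes with full precision so
fixed-seed session directories are byte-identical across runs.

# Known limitations

* The generator's artifact model is linear and stationary; real motion
  artifacts can be wavelength-dependent in ways an affine fit cannot
  remove.
* The correlation analysis assumes one global coupling latency per
  session; latency drift within a session would blur the recovered peak.
* The evoked-response classifier assumes a single dominant movement
  direction and clean baselines; it is not a general movement segmenter.
* The paired real-versus-null test inherits the anti-conservativeness
  described above when used with an averaged many-shuffle null.
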