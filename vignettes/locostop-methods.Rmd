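---
title: "Methods: locomotor event detection, calcium trace statistics and population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locomotor event detection, calcium trace statistics and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(locostop)
library(dplyr)
```

`locostop` implements a complete analysis chain for micro-endoscopic calcium
imaging recorded while an animal starts, stops and grooms spontaneously:
behavioural event detection from pose-tracking landmarks, trace processing,
per-cell significance testing against shuffled event times, cell
classification and composition tests, and population decoding of the
locomotor state. This vignette explains each model and procedure, its
assumptions, the tunable parameters and their defaults, and the design
choices made where more than one reasonable convention exists.

## Behavioural side

### Oriented speed

Freely-moving rodents are tracked by three landmarks: the two ears and a
spine point. The body orientation at frame $i$ is the unit vector
$\mathbf{u}_i$ from the spine point to the ear midpoint, and the oriented
speed is the projection of the ear-midpoint displacement on it:

$$v_i = \frac{(\mathbf{m}_i - \mathbf{m}_{i-1}) \cdot \mathbf{u}_i}{\Delta t},$$

signed so that backward translation (e.g. on a treadmill belt) is negative.
The ear midpoint serves as the body centroid for displacement; this is a
convention (the tracked point is configurable in principle) and any point
rigidly attached to the head works equally for straight-line motion. The
first frame copies the second so the trace keeps the video length. Frames
with a degenerate orientation (all landmarks coincident, e.g. a tracking
glitch) carry the last well-defined orientation forward.

States are assigned per frame by fixed thresholds: *forward* above
+3 cm/s, *backward* below −3 cm/s, *stationary* in between. The threshold is
an argument (`forward_thresh`, `backward_thresh`) because its exact value
depends on camera calibration; 3 cm/s is the default. No smoothing is
applied to the speed before thresholding by default; a user who needs it can
smooth the landmark track upstream.

### Event definitions

All duration criteria are converted to whole frames with round-half-up and
evaluated at frame resolution on the run-length encoding of the state
sequence, so sub-frame excursions cannot reset a run.

* **Stop** — onset of a stationary period of ≥ 200 ms following a forward
  run of ≥ 250 ms whose average speed exceeds 5 cm/s (selects genuine
  supra-threshold runs). Onset = first stationary frame.
* **Long stop** — stationary ≥ 3 s after a run of ≥ 100 ms, with *no*
  average-speed condition (keeps more of the rarer long arrests).
* **Start** — first forward frame of a locomotion period of ≥ 200 ms after a
  stationary period of ≥ 250 ms whose mean absolute speed is below 2 cm/s.
  The absolute value makes slow drift in either direction disqualifying.

`valid_periods` (a `start_s`/`end_s` table) restricts detection and all
downstream statistics to analysable epochs — for treadmill sessions, the
treadmill-engaged periods. Events are filtered by their onset falling inside
a period; run/immobility durations are still measured on the full trace.

Treadmill stops are typically scored manually frame-by-frame (backward belt
translation defeats speed-threshold detection); `read_annotations()` ingests
such annotations, validates types and bounds, and tags provenance.

## Calcium traces

Traces are ΔF/F (fluorescence normalised by its time-averaged mean, minus
one) at 20 Hz. Three linear operations are provided:

* `dff_normalize()` — $x / \bar{x} - 1$; fails on non-positive means.
* `gaussian_smooth()` — unit-area truncated Gaussian kernel. The "150 ms
  half-width" is interpreted as the half-width at half-maximum, i.e.
  $\sigma = 0.150 / \sqrt{2 \ln 2} \approx 0.127$ s; this is the most common
  reading of "half-width" and is exposed as `half_width_s`. The kernel is
  truncated at ±4σ and renormalised over its in-bounds support near the
  edges, so constants pass through unchanged everywhere.
* `deconvolve()` — first-order inversion of the indicator decay,
  $S_d = \tau\, dS/dt + S$ with $\tau = 0.5$ s (a typical GCaMP6s decay
  time). The derivative uses central differences (one-sided at the edges):
  the continuous equation does not prescribe a discretisation, and central
  differences make the estimate lag-symmetric. The indicator's 50–100 ms
  *rise* time is not cancelled, so the deconvolved signal still lags the
  true rate by up to two frames at 20 Hz. Deconvolution exactly inverts the
  exponential convolution in continuous time; at 20 Hz on smooth inputs the
  residual relative RMS is of order $10^{-4}$ (tested against a fine-grid
  ODE oracle).

## Per-cell event statistics

### Event-triggered average

Peri-event windows are half-open, $[t_0 - 0.25, t_0 + 1.25)$ s by default
(1.5 s total, starting 0.25 s before onset); grooming analyses of sustained
activity use a 4.25 s window. Events whose window is not fully covered by
the recording are dropped and counted. The peak, trough and time-to-peak
(ΔT) are read off the across-event mean; SEM is reported per frame and
flagged undefined for a single event.

### Shuffle (resampling) test

Significance of a cell's peri-event modulation is judged against event-time
shuffles: each of 1000 shuffles draws the observed number of pseudo-onsets
uniformly among allowed frames (onset within `valid_periods`, full window
inside the recording, no minimum separation — pseudo-events may overlap),
and recomputes the event-average maximum and minimum. The cell is *excited*
if its observed maximum strictly exceeds the 95th percentile (type-7) of
shuffled maxima and *inhibited* if its observed minimum falls strictly below
the 5th percentile of shuffled minima. Two deliberate conventions:

* "Outside 95% of the shuffles" is read as two one-sided tests at 5% each,
  matching the separate excited/inhibited calls; a stricter 2.5%-per-tail
  variant is available by passing `alpha = 0.025`.
* Pseudo-*event times* are drawn (event count preserved) rather than
  circularly shifting the trace; this matches the idea of shuffling event
  times "with respect to the calcium data" and keeps the trace's
  autocorrelation intact.

Ties lose: on a constant trace every shuffle equals the observation and
neither flag is set. Under the null the flag rate is calibrated at the
nominal 5% per direction (checked on 200 simulated noise-only cells). No
multiple-testing correction is applied across cells by default, matching
common practice for per-cell shuffle tests in this literature; users can
correct the reported extremities themselves if desired.

Cells flagged in *both* directions (possible, since the two tails are tested
separately) are assigned the direction with the more extreme shuffle
percentile, and the conflict is reported — three-way classification
(excited / inhibited / uncorrelated) admits no dual category.

### Activation probability

The per-event reliability of a cell: an event is "coded" when the trace
maximum in its window strictly exceeds 5 SD of the baseline. The baseline is
every frame outside all event windows (within `valid_periods` when given) —
the natural operationalisation when no explicit baseline epoch exists; it is
overridable via `baseline_frames`. The probability is coded events over
total events. One degenerate case is resolved deliberately: an identically
constant trace has zero baseline SD *and* zero peaks, and returns
probability 0 (nothing is ever coded); a non-constant trace whose chosen
baseline happens to have zero variance is an error, because the threshold
would be meaningless.

### Kinematic correlations

`stop_kinematics()` summarises the second before each event (mean speed,
peak deceleration, preceding run duration) and `kinematic_correlation()`
relates per-event response peaks to these covariates by Pearson correlation
with a permutation p-value (1000 re-pairings, two-sided on |r|). At least 5
events with defined kinematics are required; zero-variance covariates are
flagged rather than propagating `NaN`.

## Cell classes and composition

Per-cell class labels feed a group × class contingency table (typically
implant location × {excited, inhibited, uncorrelated}), tested with the
Freeman–Halton exact r×c test: the two-sided p-value is the total
multivariate-hypergeometric probability of all tables with the observed
margins that are no more probable than the observed table. The "probability
≤ observed" two-sided criterion matches the widely used implementations of
this test. Enumeration is exhaustive (the grand total is capped by
`enum_limit`, default 200, ample for cohort-scale tables); ties are compared
in log space with a 10⁻⁹ tolerance, far below any genuine probability gap at
these totals yet far above floating-point noise. The implementation is
validated against the hypergeometric closed form on 2×2 tables and against
an independent binomial-coefficient oracle on every 2×3 table with total
≤ 12.

`cross_context_compare()` and `start_stop_pairing()` pair per-cell results
across contexts (treadmill vs open field) or behaviours (stops vs starts),
keeping cells significant in at least one member of the pair — cells
significant in neither carry no information about consistency — and counting
same-sign and opposite-sign modulation among cells significant in both.

## Population decoding

`build_population_matrix()` stacks per-frame activity vectors (smoothed
ΔF/F by default — the choice of input variant is the caller's) with binary
labels walking = forward, stationary = 0; backward frames are excluded as
ambiguous. `jackknife_train_eval()` fits a linear maximum-margin classifier
(hinge loss, L2 regularisation, class-balanced weights; cost fixed at 1, no
tuning) on a random contiguous 80% chunk of valid frames and evaluates
decision values on the held-out 20%, repeating 5 times and averaging the
ROC AUC. Contiguous chunks — rather than i.i.d. frame sampling — limit
information leakage through the calcium signal's autocorrelation. The ROC is
computed by threshold sweep; the AUC equals the normalised Mann–Whitney
statistic (ties counted ½) and is verified against a pairwise-comparison
oracle.

The frame-wise predicted state used by `unpredicted_stops()` comes from a
model fitted on all valid frames (an in-sample readout, appropriate for a
diagnostic rather than a performance claim). A stop is *unpredicted* when no
frame in the 1.25 s after its onset is decoded stationary; since no standard
criterion exists for a "predicted" event, this documented rule is the
package's own.

## Synthetic generator

The generator emulates the structure of this kind of experiment so that
every stage can be tested against known ground truth:

* **Behaviour.** Alternating immobility/locomotion intervals with durations
  drawn from truncated exponentials (defaults: bouts mean 5 s in [1, 20];
  immobility mean 2 s in [0.5, 10]; 10 min sessions), cruising at 15 cm/s
  with 100 ms linear ramps at bout edges — the ramps give pre-stop
  deceleration a defined value for kinematic correlations. Landmarks follow
  a minimal geometry (ear midpoint on the trajectory, ears 1.5 cm apart,
  spine 2 cm behind along the heading) that reproduces the speed profile
  exactly through `oriented_speed()`; the emitted speed trace *is*
  `oriented_speed(landmarks)`, so trace and track cannot disagree. Grooming
  epochs only occur inside immobility periods (grooming and locomotion are
  mutually exclusive), entering each qualifying immobility period with
  probability `grooming_prob`.
* **Ground truth on the emitted clock.** Ground-truth stop/start onsets are
  the state-transition frames of the emitted trace (scheduled durations
  always satisfy the detection criteria, and classification happens at frame
  resolution), so round-trip tests compare detector output to a ground truth
  expressed in the same clock and the ±1-frame recovery requirement is
  meaningful rather than vacuous.
* **Cells.** Planted classes: stop-excited (low 0.2 a.u./s baseline, rate
  bump of `response_amp` for 0.4 s at each responded stop — through the
  whole stationary state when `sustained`), stop-inhibited (tonic 2 a.u./s
  baseline suppressed to 5% for 1.25 s at responded stops — inhibition is
  only visible in ΔF/F if there is tonic activity to suppress),
  start-excited, grooming-excited, and uncorrelated (event-independent bumps
  at 0.1 /s). Event-wise reliability `reliability_p` (default 0.8) makes
  responses probabilistic, as observed for single stop events in vivo.
* **Calcium.** Poisson events drawn per frame from the rate, convolved with
  a unit-peak difference-of-exponentials kernel
  $k(t) = e^{-t/0.5} - e^{-t/0.075}$ (GCaMP6s-like decay and rise), plus
  Gaussian white noise (`noise_sd`, default 0.05 ΔF/F). White Gaussian noise
  is the simplest defensible model; real miniscope noise also contains
  shared, movement-locked and photobleaching components that the generator
  does *not* emulate. Transient amplitudes in ΔF/F are free parameters — no
  published per-cell amplitudes exist for this preparation — so recovery
  tests state their planted amplitudes explicitly.

Because the generator omits tracking jitter, neuropil contamination and
non-stationary noise, passing recovery tests demonstrates the correctness of
the algorithms under their stated assumptions, not robustness to every
artefact of real data.

Everything is reproducible: one integer seed determines the schedule, the
reliability draws, the Poisson events and the noise; analysis randomness
(shuffles, decoder splits) takes separate seed arguments.

## Worked example

```{r example}
cfg <- sim_config(duration_s = 150, seed = 1)
ds <- simulate_dataset(cfg, default_cohort(6))
stops <- detect_stops(ds$behavior$speed)
nrow(stops)

sm <- gaussian_smooth(ds$traces)
res <- resampling_test(sm$cell_01, stops, rate_hz = 20, seed = 1)
glance(res)

ea <- event_triggered_average(sm$cell_01, stops, rate_hz = 20)
autoplot(ea)
```

```{r pipeline}
out <- run_pipeline(cfg, default_cohort(6), n_shuffles = 200, decode = FALSE)
glance(out)
```

## Numerical choices and problem sizes

* Duration thresholds are converted to frames by round-half-up; detection is
  deterministic given the state sequence.
* Quantiles use R's default type 7; significance requires strict
  inequality, so ties are conservative.
* The validation suite runs the shuffle-test calibration on 200 null cells
  with 60 events and 1000 shuffles, the power check over 100 planted-cell
  seeds, the detection round trip over 50 simulated two-minute sessions, and
  decoding on 200 s populations of 8 cells — sizes chosen to make the
  binomial tolerances of the checks meaningful on a single CPU.

## Known limitations

* The pipeline consumes extracted traces; source extraction, demixing and
  motion correction are upstream concerns.
* Treadmill stop detection from speed is not attempted (backward belt
  translation); use annotations there.
* The exact r×c test enumerates tables exhaustively and is intended for
  cohort-scale counts (total ≲ 200 with few rows/columns), not large tables.
* The decoder is deliberately minimal (linear, fixed cost); it quantifies
  how informative the population is, not the best achievable decoding.
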