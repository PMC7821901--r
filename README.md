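# locostop

Analysis of micro-endoscopic (miniscope) calcium imaging recorded while an
animal spontaneously starts, stops and grooms. The package is aimed at
systems-neuroscience users who have (i) body-landmark tracking of a
freely-moving animal and (ii) per-cell ΔF/F traces from the same session,
and who want to ask: which cells are significantly excited or inhibited at
locomotor stops and starts, how reliably does each cell respond, does the
cell-class composition differ between implant locations or contexts, and how
well does the population as a whole encode the locomotor state?

## What it computes

**Behaviour.** Oriented locomotor speed from ear/spine landmarks — the
displacement of the ear midpoint projected on the body axis
(spine → ear-midpoint vector), signed so backward translation is negative —
and rule-based events on the thresholded state sequence
(forward > 3 cm/s, backward < −3 cm/s, stationary otherwise):

* stop: ≥ 200 ms immobility after a ≥ 250 ms run with average speed > 5 cm/s
* long stop: ≥ 3 s immobility after a ≥ 100 ms run (no speed-average rule)
* start: ≥ 200 ms locomotion after ≥ 250 ms stationary with mean |speed| < 2 cm/s

**Traces.** ΔF/F normalisation (`x/mean(x) − 1`), Gaussian smoothing (150 ms
half-width at half-maximum), and first-order deconvolution of the indicator
decay, `S_d = τ·dS/dt + S` with τ = 0.5 s (GCaMP6s-like).

**Per-cell statistics.** Event-triggered average (mean ± SEM, peak, trough,
time-to-peak in a 1.5 s window starting 0.25 s before onset); a shuffle test
that compares the observed event-average extrema with 1000 draws of
pseudo-event times (excited if the max beats the 95th percentile of shuffled
maxima, inhibited if the min undercuts the 5th percentile of shuffled
minima); activation probability (fraction of events whose peri-event peak
exceeds 5 baseline SDs); and permutation-tested Pearson correlations between
per-event peaks and pre-stop kinematics.

**Population statistics.** Three-way cell classification
(excited/inhibited/uncorrelated); Freeman–Halton exact r×c test for
group × class composition tables (exhaustive enumeration; the two-sided
p-value sums the probabilities of all margin-compatible tables no more
probable than the observed one); paired comparisons across contexts and
across behaviours; and a jack-knifed linear SVM that decodes walking vs
stationary frame-by-frame, summarised by ROC/AUC over five random
contiguous 80/20 splits.

**Synthetic generator.** `simulate_dataset()` produces coupled landmark
tracks, speed traces, ground-truth event lists and GCaMP6s-like ΔF/F traces
from planted cell classes (stop-excited with event-wise reliability,
stop-inhibited, start-excited, grooming-excited, uncorrelated), so every
stage of the pipeline has a parameter-recovery test surface.

## Worked example

```r
library(locostop)

cfg <- sim_config(duration_s = 150, seed = 1)          # 2.5 min synthetic session
ds  <- simulate_dataset(cfg, default_cohort(6))        # 6 planted cells
stops <- detect_stops(ds$behavior$speed)
nrow(stops)
#> [1] 17

sm  <- gaussian_smooth(ds$traces)
res <- resampling_test(sm$cell_01, stops, rate_hz = 20, seed = 1)
res
#> Shuffle test (17 events, 1000 shuffles, alpha = 0.05/direction)
#>   max 1.9065 vs q95 0.7206 -> excited: TRUE
#>   min 0.1379 vs q5 0.0802 -> inhibited: FALSE

activation_probability(sm$cell_01, stops, rate_hz = 20)
#> Activation probability: 13 / 17 events coded (p = 0.765, k = 5 SD)

out <- run_pipeline(cfg, default_cohort(6), n_shuffles = 200)
out
#> Pipeline result: 6 cells, 39 events
#>   stop classes: excited = 2, inhibited = 2, uncorrelated = 2
#>   composition test P = 1
#>   decoding mean AUC = 0.736
```

The first cell (planted stop-excited, reliability 0.8) is flagged excited:
its event-average peak (1.91 ΔF/F) far exceeds the 95th percentile of the
shuffled-event maxima (0.72), and 13 of its 17 stops show a supra-threshold
transient (activation probability 0.76). The pipeline recovers the planted
cohort composition exactly (2 excited / 2 inhibited / 2 uncorrelated) and
the population decodes walking vs stationary above chance (AUC 0.74).
`tidy()`, `glance()` and `autoplot()` methods give tabular and graphical
views of every result object.

A committed tiny dataset (60 s, 4 cells) lives in
`inst/extdata/tiny_dataset/`; regenerate or scale it with `make_fixtures()`,
and load it with `read_dataset()` or `run_pipeline(input_dir = ...)`.

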