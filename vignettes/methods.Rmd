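---
title: "Methods: TRF encoding models with noise-corrected evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRF encoding models with noise-corrected evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions it makes, and where the genuinely open design choices were
decided. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The encoding model

A temporal receptive field (TRF) predicts the spike count of one
multi-unit in one time bin as a linear function of a causal window of
feature values — hidden-layer activations of an audio network, a
cochleagram, or any other time × dimension matrix resampled to the bin
rate. The window is 250 ms; the number of lags is `round(window * rate)`
with round-half-up, so 5 lags at 20 Hz (50-ms bins) and 13 at 50 Hz
(20-ms bins). The window is causal (lags reach into the past only):
feature values cannot depend on future spikes physiologically, and a
one-sided convention is the testable one. Designs are zero-padded at
each stimulus onset so lags never mix adjacent stimuli.

Weights minimize L2-penalized squared error. The penalty is selected by
3-fold cross-validation over 21 log-spaced values from 1e-5 to 1e15;
the final model is refit on all training data at the winning penalty.
Three numerical decisions here were open and are fixed as follows:

* **Folds are contiguous temporal blocks**, not shuffled bins. Spike
  counts and features are strongly autocorrelated; shuffled folds leak
  information between train and validation and bias the penalty low.
* **Features are standardized per column on the training folds** before
  penalization, so one penalty scale is meaningful across feature sets
  with very different units; returned weights are mapped back to the
  original scale.
* **The intercept is never penalized** (it absorbs the baseline firing
  rate).

The ridge path is computed from one SVD per fold, shared by the whole
penalty grid and — because every unit at a given layer shares the same
design — by all units at once. The SVD route is the implementation; the
test suite checks it against the direct closed-form solution
`solve(X'X + lambda I, X'y)` on random small problems to 1e-6 relative
error, and checks that a 1e15 penalty shrinks weights below 1e-6 of the
least-squares norm. An all-zero design yields a flagged model with zero
weights rather than an error, so population loops degrade gracefully.

## Reliability, unit selection, and the noise ceiling

Trial-to-trial variability caps what any noise-free model can achieve,
so model evaluation is anchored to a per-unit reliability estimate. For
each of the repeat-set stimuli, two distinct trials are drawn at random;
the first members are concatenated (in a random stimulus order shared by
both sequences) into a long sequence `U`, the second members into `V`,
and the Pearson correlation of `(U, V)` is one sample of the *true*
distribution. For the *null*, `V` is first rotated by half its length —
a circular shift preserves the marginal histogram exactly while
destroying temporal alignment. The procedure is repeated `R` times
(100,000 in full-scale use; the tests run at 1,000–10,000). Resamples in
which either sequence is constant have no defined correlation; they are
excluded and counted, never set to zero.

A unit is **tuned** if a one-sided Wilcoxon rank-sum test finds the true
distribution greater than the null at p < 0.05, and **well-tuned** if in
addition the distribution means are separated by at least δ = 0.5 null
standard deviations (boundary inclusive, with a 1e-12 round-off guard;
δ = 1 is the conventional robustness reprise). The **ceiling** is the
mean of the true distribution, and a model's mean held-out correlation
is corrected as `r / sqrt(ceiling)`: a trial-to-trial correlation
contains two independent noise sources where a model–neuron correlation
contains one, hence the square root. Ceilings at or below 1e-3 are
flagged uncorrectable and the unit is excluded from corrected scores —
clipping would silently manufacture huge corrected values.

### A calibration caveat the tests quantify

The rank-sum test is applied to `R` resampled correlations that reuse
the same underlying trials and are therefore correlated with each other.
Conditional on a finite trial set, even a stimulus-unlocked (gain-0)
unit shows a small chance offset between its true and null resampling
distributions, and with `R` = 10,000 "samples" the rank-sum test
resolves offsets far smaller than that. The consequence, measured by the
acceptance suite on 500 simulated gain-0 units, is a one-sided rejection
rate near 0.4 rather than the nominal 0.05 — and it grows with `R`
(about 0.17 at R = 500, 0.37 at 2,000, 0.46 at 10,000). The nominal
p-value of this test should therefore be read as a descriptive screen,
not calibrated inference; `R` is always reported alongside p. The same
simulations show the δ-gap criterion is what actually controls
selection: its false-positive rate on gain-0 units is measured at 0/500,
because chance offsets are an order of magnitude smaller than half a
null standard deviation. This is precisely why a gap criterion on top of
the rank-sum screen is needed at all.

## Evaluation and model comparisons

Held-out scoring concatenates the model's predictions for the repeat
stimuli into one long sequence (fixed stimulus order) and the recorded
responses into one long sequence per repeat index, all in the same
order; the score is the mean of the per-repeat Pearson correlations,
then noise-corrected. Comparisons across models are paired per unit:
for each layer, trained-vs-untrained and trained-vs-STRF Wilcoxon
signed-rank tests — 2×L tests per model — with Benjamini–Hochberg
control within that family at level 0.01. Two open choices:

* **Sidedness**: tests are two-sided with the direction of the median
  paired difference reported. A one-sided reading ("trained is
  superior") presumes the conclusion; the two-sided p with a sign is
  strictly more informative and at most a factor of two conservative.
* Units with undefined scores in either member of a pair are dropped
  pairwise and counted.

The STRF-to-model **correlation ratio** is provided as the alternative
report: the common ceiling normalizer cancels algebraically, which the
tests verify numerically.

## Population analyses

**Layer preference**: for each unit, the layer with the highest
corrected correlation; ties break to the shallowest layer (a
conservative choice against spurious depth). Depth fraction is the
1-based layer index over the total depth, so it lies in (0, 1]. The
hierarchy contrast is a one-sided rank-sum test that non-primary units
have larger depth fractions than primary units. When several hierarchies
are analyzed, preferences are pooled per (unit, stack) pair with equal
weight, and per-stack breakdowns are available from the same table.

**Time scale**: layer features already at the bin rate are zero-phase
low-pass filtered at each cutoff, the TRF is *refit* per cutoff (the
filtered features are the model's input, so refitting, not filtering
predictions, is the honest operation), and held-out corrected
correlations are recomputed. The best cutoff maximizes the median across
units; the "indistinguishable set" contains every cutoff whose paired
signed-rank test against the best has p ≥ 0.01. A cutoff at the bin-rate
Nyquist bypasses the filter entirely, so the top of the sweep reproduces
unfiltered scores exactly.

## The synthetic-session generator

The generator produces exactly the statistical structure the analysis
assumes, with known ground truth:

* **Schedules** mirror the standard designs: 489 once-presented plus
  10 × 11 repeated stimuli of ~1.6 s (speech-like), or 292 plus 11 × 15
  of ~1.0 s (vocalization-like); durations jitter uniformly; bins per
  stimulus are `ceiling(duration / bin_width)` (the trailing partial bin
  is kept).
* **Features** are a smoothed broadband Gaussian base process at 100 Hz
  pushed through a stacked hierarchy: each deeper layer is `tanh` of a
  random causal temporal convolution of the previous one, downsampled by
  its stride, so sampling rates decline with depth. "Trained" stacks use
  structured kernels (random mixtures of temporal smoothing and
  differencing profiles at saturating scale); "untrained" uses small
  random weights, under which layers are nearly linear maps of their
  inputs. Weights are stored so they can be re-initialized or permuted
  within layer; permuting structured kernels destroys their organization
  while preserving the weight histogram, and measurably degrades how
  well deep layers linearly encode the base signal relative to
  re-initialization.
* **Units** are Poisson: the drive is the unit's true 250-ms TRF applied
  to its target layer, calibrated to unit variance session-wide; the
  rate is `baseline + gain * max(drive, 0)` (rectification keeps rates
  non-negative without clipping artifacts) and counts are drawn
  independently per presentation, so repeats share the stimulus-locked
  rate. Poisson noise was chosen because it yields an analytic
  reliability target — for per-bin expected counts with variance s² and
  mean m, the trial-to-trial correlation is s²/(s² + m) — which the
  tests verify by Monte Carlo. Default gains (20–60 spikes/s per unit
  drive) and baselines (2–10 spikes/s) put most units in a well-tuned
  regime with ceilings around 0.3–0.6, a realistic operating range; no
  recorded firing-rate distributions were available to calibrate
  against, so these are stated, not fitted.
* **Region labels**: primary units draw their target layer from the
  shallow half of the hierarchy, non-primary from the deep half, with
  25% cross-over — a "soft" hierarchy that the rank-sum contrast should
  detect without the distributions being separable.

For the band-limited time-scale validation, the base process is
band-limited with an exact FFT brickwall rather than an IIR filter: the
claim under test is "no drive above the band", and an IIR transition
band would violate that premise. The drive band (2 Hz) is kept well
inside the smallest above-band cutoff tested (5 Hz) because the sweep's
own 4th-order zero-phase Butterworth attenuates its passband edge, and a
13-tap TRF cannot fully re-equalize that; with the band well inside the
passband, cutoffs at and above 5 Hz are genuinely equivalent.

What the generator does **not** emulate: real network representations or
receptive-field sizes, non-Poisson spiking (bursting, refractoriness,
adaptation), slow non-stationarity across a session, correlated noise
across units, or any specific acoustic-feature selectivity. Passing
tests therefore establish that the *pipeline* recovers ground truth
under its own assumptions — not that those assumptions hold in cortex.

## I/O and numerical conventions

* Feature resampling uses windowed-sinc interpolation (Hann window,
  unit-sum kernels, cutoff at the lower Nyquist), accurate to ~1e-2
  against closed-form sinusoids away from edges and exact on constants.
* The low-pass is a 4th-order zero-phase (forward–backward) Butterworth;
  edge-replication padding of ten cutoff periods suppresses boundary
  transients. Cutoff equal to Nyquist returns the input unchanged.
* The cochleagram uses 211 gammatone-magnitude filters spaced uniformly
  on the ERB-rate scale over 50–8000 Hz, Hann-windowed frames with 87.5%
  overlap (400-ms window, 50-ms hop at the default 20-Hz frame rate),
  and log compression after clipping at 1e-5 of the maximum amplitude —
  omitting the log costs a great deal of predictive power downstream,
  and the floor keeps silence finite.
* Sessions serialize to a plain-text directory (CSV matrices, JSON
  schedule/metadata) and round-trip exactly; a minimal mono 16-bit PCM
  WAV reader/writer covers audio.
* Every stochastic stage takes an explicit seed, and pipeline stages
  derive disjoint seed streams from one master seed, so identical
  configs produce identical files.

## Problem sizes used by the checks

The test and acceptance simulations are sized for desk-scale runs while
keeping each effect far above its Monte-Carlo noise: 200 units for layer
recovery (60 training stimuli of 1.6 s at 50-ms bins), 200 units per
region group for the hierarchy contrast, 24 units for the time-scale
sweeps (20-ms bins), 500 gain-0 units at R = 10,000 for null
calibration, and 10,000-bin Gaussian surrogates for ceiling recovery
(target within 0.02). Full-scale analyses would use the same code with
larger R and sessions.

## Known limitations

* The rank-sum tuned test is anti-conservative at large `R` (measured
  above); rely on the δ-gap criterion for selection.
* The cochleagram is a generic gammatone-magnitude frontend, not a
  reproduction of any specific model's input pipeline; alternative
  frontends can be passed through the same `feature_matrix` interface.
* Comparisons pool units; there is no cross-session or cross-animal
  mixed-effects structure.
* Reliability p-values inherit every caveat of treating resamples as
  independent; the per-unit table reports `R` and the exclusion count so
  downstream users can judge.
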