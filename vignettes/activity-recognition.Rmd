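---
title: "Activity recognition from body-worn accelerometers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity recognition from body-worn accelerometers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harwear)
```

## The problem

Human activity recognition (HAR) infers which physical activity a person is
performing from streams of body-worn sensor data. `harwear` implements the
standard four-stage recognition chain for a three-device wearable setup —
accelerometers (plus unused gyroscope, magnetometer and ECG channels) on
the chest, right wrist and left ankle, sampled at 50 Hz — and the two
protocols used to evaluate such a recognizer: repeated stratified k-fold
cross-validation on recorded data ("offline") and delay-aligned scoring of
a streaming recognizer ("online").

The pipeline is:

1. **Data model.** A `har_session` holds metadata (devices → sensors →
   axes, units, interval, rate) once, plus a samples × channels matrix with
   a per-sample integer activity label (0 = null/transition, 1–12 = the
   activity set: standing, sitting, lying, walking, stairs, waist bends,
   arm elevation, knees bending, cycling, jogging, running, jumping).
   Sessions serialize to whitespace-delimited log files (no header, label
   last) and to JSON documents.
2. **Preprocessing.** Integer-factor decimation and linear-interpolation
   upsampling (`downsample()`, `upsample()`). The recognition model itself
   applies no preprocessing, so these are utilities, not defaults.
3. **Segmentation.** Non-overlapping windows of `floor(W · fs)` samples
   (`make_windows()`), default W = 2 s → 100 samples at 50 Hz; an
   equivalent streaming buffer (`har_stream()`/`stream_push()`) emits
   bitwise-identical windows at runtime.
4. **Features.** Per channel and window: mean, standard deviation, maximum
   and minimum by default — 9 acceleration channels × 4 statistics = 36
   features. Variance, zero-crossing and mean-crossing counts are also
   available.
5. **Classification.** `har_train()` fits a C4.5-style decision tree
   (default), Gaussian naive Bayes, or the ZeroR majority baseline.

## Evaluation protocols

**Offline.** `har_cv()` repeats stratified 10-fold cross-validation
(default 100 repetitions; examples in this package use 10 — the estimate is
already stable at that size for the synthetic data, and a run completes in
seconds). Each repetition uses seed `base_seed + r` for its fold shuffle.
Fold confusion matrices are **summed** over folds and repetitions, and the
per-class metrics are computed once on the aggregate, which corresponds to
reporting a single per-activity table. For a K-class confusion matrix `C`
(rows = actual), the one-vs-rest metrics per class are

- SE = TP/(TP+FN), SP = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN),
- F = 2·PPV·SE/(PPV+SE),

with any 0/0 ratio reported as 0 and flagged (`degenerate`), never as a
silent `NaN`. Printed reports round to two decimals; objects keep full
precision.

**Online.** A streaming recognizer emits a label at each window *end*. On
average that prediction describes the window's temporal *centre*, so
predictions must be shifted by `segmentation_delay(W) = W/2` — 1 s for 2-s
windows — before comparison with ground truth. `online_evaluate()` compares
each prediction against the truth span `[end_time − W, end_time)` and
excludes spans that are not unanimous (transitions between activities) or
that touch the null class, because no null-class rejection stage exists.
With correct alignment, online scoring of a batch-equivalent recognizer is
exactly the offline confusion on the shared non-transition windows — a
property the test suite asserts bitwise.

## The synthetic data generator

Real recordings of this kind are large and subject-specific; the package
instead ships a seeded generator whose defaults encode the *qualitative*
structure such datasets exhibit, so the full pipeline can be exercised and
tested end to end:

- per device and activity, acceleration is gravity orientation (unit vector
  × 9.81 m/s²) + a per-axis sinusoid (amplitude, shared fundamental
  frequency, phase) + Gaussian noise;
- the three static postures differ only in gravity orientation;
- the locomotion family shares its waveform with cadence and amplitude
  increasing from walking (1.5 Hz) through jogging (2.5 Hz) to running
  (3.0 Hz), with jogging and running deliberately close in amplitude and
  noisier (σ = 0.8 m/s²), making them the most confusable pair — the
  structure observed in real recordings of these activities;
- waist bends and knees bending share a low-frequency trunk sway, the
  second characteristically confusable pair;
- subjects differ by two multipliers drawn once per subject,
  `amplitude_scale ~ lognormal(0, 0.1)` and `cadence_scale ~
  lognormal(0, 0.05)`;
- ECG leads carry a fixed quasi-periodic placeholder and gyro/magnetometer
  channels labelled filler signals; none are used for recognition;
- optional null-labelled gaps between activities exercise transition
  exclusion in the online protocol.

Amplitudes, cadences and noise levels are declared constants chosen to be
plausible for body-worn accelerometry, not estimates fitted to any real
recording. All randomness flows from one root seed (profiles first, then
session `i` from `seed + 1009·i`).

**What passing tests do and do not show.** The generator reproduces class
geometry (static/dynamic contrast, cadence-ordered locomotion, the two hard
pairs) but not the messiness of real sensor data: orientation drift, sensor
detachment, within-bout tempo changes, harmonics and impacts of real gait,
or subject-specific movement idiosyncrasies. A near-perfect macro F-score
on synthetic sessions therefore demonstrates that the pipeline is wired
correctly and that the protocol arithmetic is right — not that the
classifier would reach the same numbers on real recordings.

## Numerical and design choices

- **Variance** uses the sample (N−1) denominator, matching common
  machine-learning toolkits.
- **Crossing counts.** `zcr` counts sign changes between consecutive
  samples; a zero inherits the most recent nonzero sign and leading zeros
  count as positive (a frozen, documented convention — definitions of these
  features vary across the literature). `mcr` is `zcr` of the mean-centred
  window. Counts are not normalised by window length.
- **Windowing.** Trailing partial windows are discarded. The majority label
  tie-break goes to the tied label occurring earliest in the window, which
  is deterministic and reduces to "the first row's label" whenever that
  label is tied.
- **Upsampling** interpolates linearly and copies the left neighbour's
  label; interpolation at original grid points returns the original rows
  exactly, so `downsample(upsample(x, k), k)` is an identity.
- **Fold assignment** is stratified by default (each class spread as evenly
  as possible over folds); a class smaller than k raises an error advising
  `stratified = FALSE` rather than silently degrading.
- **Decision tree.** Induction is delegated to `rpart` with
  information-gain splits; defaults `min_leaf = 2`, pruning on with
  `cp = 0.01`, `prune = FALSE` grows the full tree (used to prove exact
  separation on noiseless toys). The exact hyperparameters of tree
  implementations differ across toolkits; these defaults are this package's
  documented choice.
- **Timestamps** are synthesized as `i/fs` because log files carry no time
  column; gap validation uses a 1e-9 s tolerance. Log values are written
  with 17 significant digits for lossless roundtrips.
- **Degenerate inputs.** Empty matrices segment to an empty window list; a
  single-class training set yields a constant single-leaf tree; metric
  ratios over empty denominators are 0 with a flag.

## Problem sizes used in tests and the reproduction script

The shipped end-to-end check uses 10 subjects × 12 activities × 30 s at
50 Hz (18 000 samples/subject, 1 800 windows, 36 features), a stratified
10-fold CV with 10 repetitions, and an online phase with 5 fresh subjects
with 3-s null gaps. Ten repetitions rather than 100 is the package's
default for examples; the aggregate estimate on this generator changes only
in the third decimal beyond that, and the full 100 can be requested via
`repetitions = 100`.

## Known limitations

- Feature extraction is per-axis; magnitude-signal features, frequency-
  domain features and heuristic features are out of scope.
- No anti-alias filtering before decimation; compose `upsample()` ∘
  `downsample()` for rational factors.
- Leave-one-subject-out validation and between-classifier significance
  testing are not implemented.
- Published per-activity tables from real recordings cannot be reproduced
  from synthetic data; reported tables for such systems also round SE/PPV
  to two decimals, so a handful of printed F values are internally
  inconsistent at that precision (the package's `fscore()` arithmetic makes
  this visible).

## A worked example

```{r example, eval = FALSE}
sessions <- generate_dataset(3, har_schedule(1:12, 10), 50, seed = 1)
features <- bind_features(lapply(sessions, har_features))
cv <- har_cv(features, repetitions = 10, seed = 1)
print(cv)
```
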