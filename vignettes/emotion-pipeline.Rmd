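---
title: "Methods: EEG emotion recognition with Hjorth features"
author: "affectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG emotion recognition with Hjorth features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectr)
```

## The problem

Consumer EEG headsets make it practical to monitor the affective state of a
subject — for instance a student during a lesson — without clinical
equipment. `affectr` implements a complete recognition pipeline for that
setting: 14 channels of scalp EEG sampled at 128 Hz are segmented into
short epochs, decomposed into the clinical frequency bands, summarized by
Hjorth's time-domain descriptors, and classified into one of four emotion
classes, one per quadrant of the valence–arousal plane:

| class  | valence | arousal |
|--------|---------|---------|
| happy  | +       | +       |
| scared | −       | +       |
| calm   | +       | −       |
| sad    | −       | −       |

Per-epoch decisions are noisy, so the live ("expressive") mode aggregates
ten consecutive epoch decisions into one feedback per 15 s window by
majority vote, and attaches any instructor-stored treatment note when the
winning state is unpleasant (sad or scared).

Because the package must be testable without hardware, it ships a seedable
synthetic EEG generator whose class-conditional band powers differ across
the four classes. Everything downstream is exercised against that
generator.

## Signal model of the generator

Each channel of a synthetic recording is

$$x_c(t) \;=\; \sigma_0\, b(t) \;+\; \sigma_1 \sum_{k \in \text{bands}} g_{k c}\, n_k(t),$$

where $b(t)$ is broadband noise with a $1/f$ amplitude spectrum (low-passed
near the 43 Hz output bandwidth of the emulated headset) normalized to unit
standard deviation, $n_k(t)$ is unit-variance Gaussian noise band-limited
to band $k$, and $g_{kc}$ is the class's gain for band $k$ on channel $c$.
Defaults: $\sigma_0 = 15\,\mu\mathrm{V}$ (background excursions on the
order of ±50 µV, a realistic scalp-EEG scale), $\sigma_1 = 6\,\mu\mathrm{V}$
per unit gain, and gain 2.5 on each class's signature bands against a
baseline of 1:

* **calm** — elevated alpha on all channels,
* **happy** — elevated beta on frontal channels,
* **sad** — elevated delta and theta on frontal channels,
* **scared** — elevated theta and beta on frontal and temporal channels.

These profiles are *fixtures*, not physiological claims: they were chosen
once so that every pair of classes differs in at least one (band, channel)
mean power by well over three standard errors across seeded recordings,
which is the property that makes classification tests meaningful. Passing
tests therefore demonstrate that the pipeline recovers class structure that
is present in the data at realistic amplitudes; they do not demonstrate
recognition performance on human EEG, which carries artifacts (blinks,
EMG), nonstationarity, and far weaker class separation than the fixtures.
The generator deliberately models none of those.

## Band decomposition

The preprocessing stage restricts signals to 0.5–30 Hz and splits them
into the conventional clinical bands — delta 0.5–4, theta 4–8, alpha 8–13,
beta 13–30 Hz — which tile the envelope without overlap. The band edges are
exposed in `eeg_bands()` and configurable.

Filtering must be zero-phase: Hjorth mobility and complexity are built from
first differences, and group delay or phase distortion would bias them.
The filter is a Butterworth band-pass applied *spectrally*: the FFT of the
reflect-padded signal is multiplied by the squared analytic Butterworth
magnitude response (the equivalent of a forward–backward `filtfilt` pass),
then inverted. This has exactly zero phase at every frequency and is
numerically exact at any order — relevant because recursive realizations of
a high-order band-pass with a 0.5 Hz edge at a 128 Hz rate are unstable in
transfer-function form, and the delta band sits exactly there.

The default prototype order is 12. The choice is driven by an idempotence
requirement we impose on the filter bank: re-filtering a band-filtered
epoch with the same band must retain at least 95 % of its power, so that
band energy is a stable, well-defined quantity. Lower orders leave too much
transition-band energy (a 4th-order design retains only ~90 % on
re-filtering); order 12 satisfies the requirement across all four bands on
EEG-like input with margin, while keeping the in-band/out-of-band contract
(≥ 90 % retention of in-band tones, ≤ 1 % leakage two octaves out) that the
selectivity tests assert.

Edge effects are handled by reflect-padding (up to 3 s) before the FFT;
the padding is discarded after filtering.

## Epochs and the three feature families

Epochs are contiguous, non-overlapping windows of 192 samples (1.5 s).
That length is chosen so that (a) one full 14-channel epoch flattens to
exactly 14 × 192 = 2688 values, the published length of the filtered-signal
feature vector, and (b) ten epochs tile one 15 s decision window.

1. **Filtered-signal vectors** (`filtered_features()`): the 0.5–30 Hz
   band-limited samples of all 14 channels concatenated channel-major;
   2688 values per full epoch.
2. **Hjorth-14** (`hjorth_features()`): for each of the 14 channels and
   each of the 4 bands, the Hjorth triple — 168 values.
3. **Hjorth-6** (`hjorth_features(ep, frontal_channels())`): the same on a
   6-channel frontal/central subset — 72 values. The montage has no
   midline central electrodes, so the subset defaults to the six most
   frontal-central sites (AF3, F3, FC5, FC6, F4, AF4); it is configurable.

The Hjorth parameters (normalized slope descriptors) are computed from
population variances with unscaled first differences:

$$\text{activity} = \operatorname{var}(y), \qquad
  \text{mobility} = \sqrt{\frac{\operatorname{var}(\Delta y)}{\operatorname{var}(y)}}, \qquad
  \text{complexity} = \frac{\text{mobility}(\Delta y)}{\text{mobility}(y)}.$$

With these conventions mobility is in radians per sample: a pure sinusoid
of frequency $f$ at rate $f_s$ has mobility $2\sin(\pi f/f_s)$ and
complexity 1, which the tests verify against closed forms and against a
brute-force evaluation of the definitions. Whether Hjorth descriptors are
better computed per band or on the broadband signal is an open choice;
per band is the default (it is what makes the 168/72 layouts), and the
broadband variant is available by passing a single-band table.

A constant (zero-variance) signal has undefined mobility. In single-signal
use `hjorth_params()` raises an error; in batch feature extraction a flat
channel maps to the sentinel triple (0, 0, 0) with a warning, so one dead
electrode cannot abort a session.

## Feature ranking

`mi_rank()` estimates the mutual information between each feature and the
class label with a plug-in estimator on equal-frequency bins (default 8
bins, quantile breaks; degenerate features with fewer distinct values
collapse to fewer bins and score 0). No bias correction is applied: the
estimator is used only to *rank* features, where the small positive bias is
shared across features and harmless, and the deterministic, parameter-free
construction is worth more than unbiasedness. Ties (including the all-zero
case) break by original column index, so rankings are total and
reproducible.

## Classification

`fit_emotion_model()` supports the two classifiers of the original design:
an RBF-kernel SVM (cost 1, $\gamma = 1/p$; via `e1071`) and KNN (k = 5,
Euclidean; via `caret::knn3`). The published system left kernel and k
unstated; these are the common defaults and both are configurable. Two
implementation notes:

* **Standardization.** Hjorth activity (µV²) and mobility (dimensionless)
  differ by orders of magnitude, so features are standardized to zero mean
  and unit variance — with statistics computed from the training data only
  and frozen into the model, so cross-validation never leaks test
  information through scaling.
* **Determinism.** Model predictions must be reproducible. KNN class votes
  are read from the neighbor-vote probabilities and ties break
  deterministically in class order (a vote-tie rule delegated to a random
  stream would make `predict()` nondeterministic).

`cross_validate()` implements stratified k-fold evaluation (default 10
folds): samples are shuffled within class under the given seed and dealt
cyclically along the class-blocked order, which makes both the per-class
and the overall fold sizes differ by at most one. The report carries
per-fold accuracies and the pooled 4 × 4 confusion matrix; `tidy()` and
`glance()` give tibble summaries.

Models persist as versioned JSON holding hyperparameters, scaling
statistics, the feature layout, and the training set itself; loading refits
the deterministic classifier, so a restored model provably predicts
identically to the original. "Updating a model with new recordings" is
realized as retraining on the union of stored and new epochs — profiles
accumulate labeled epochs across sessions precisely to support this.

## Expressive mode and majority voting

`run_expressive()` replays the live loop over a stored recording: segment,
featurize with the model's own feature family, predict per epoch, and emit
one feedback per complete 15 s window (trailing partial windows produce
nothing). The feedback label is the majority vote of the window's ten
decisions; ties break toward the tied label seen most recently, favoring
the subject's current state in a monitoring context. Voting is the
system's error-reduction mechanism: if the true class wins each epoch
independently with probability 0.6, the majority over ten decisions is
correct roughly 93–95 % of the time, and the test suite verifies the
improvement over the single-epoch rate by simulation over ≥ 500 windows.

"Unpleasant" states — the negative-valence classes sad and scared — trigger
treatment lookup in the user profile; whatever instructor notes are stored
under the winning emotion are attached to the feedback.

## Training sessions and profiles

`build_manifest()` reproduces the structure of the affective-picture
protocol: 45 stimuli per class, 180 in total, each tagged with its class's
valence/arousal quadrant and a display duration (default 3 s; the original
protocol's timing is unreported). Stimulus content is deliberately absent —
only the manifest structure matters to the pipeline, and the normed picture
sets it emulates are licensed. `record_training_session()` turns a manifest
into labeled epochs through the synthetic generator, with per-entry
sub-seeds derived from one master seed.

Profiles (`new_user_profile()`) store labeled epochs, treatment history
(append-only, timestamped), and naming information; they persist as one
versioned JSON file per user and round-trip losslessly (samples to better
than 1e-6).

## Problem sizes used in the checks

The statistical checks run at sizes chosen to make their expected outcomes
sharp while staying quick: class separability uses 20 recordings of 4 s per
class; the recovery check uses 30 epochs per class (120 × 168 feature
matrix) under 10-fold CV, against a permuted-label control expected at the
0.25 chance rate of four balanced classes; the voting simulation uses 500+
windows; the ranking check uses 20 trials of 200 samples against 50 noise
features. Under the default class profiles the recovery accuracy is
essentially 1.0 — the fixtures are well separated by construction; the
scientifically meaningful content of that check is the gap to the permuted
control, not the absolute number.

## Known limitations

* The synthetic generator omits artifacts, nonstationarity,
  volume-conduction correlation between channels, and subject variability;
  results on it bound nothing about human EEG.
* Only four discrete classes are modeled; the valence–arousal plane is
  quantized to its quadrants.
* No incremental learning: model updates retrain from the stored epoch
  pool.
* The spectral filter assumes the whole epoch is available; it is applied
  to stored windows, not causally sample-by-sample, matching the 1.5 s
  decision granularity of the system.
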