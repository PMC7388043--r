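---
title: "Nocturnal cough monitoring from smartphone audio: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nocturnal cough monitoring from smartphone audio: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

Nocturnal cough frequency is a clinically meaningful but hard-to-measure
outcome: patients cannot count their own coughs while asleep, and manual
annotation of overnight recordings does not scale. This package implements a
full pipeline that turns a continuous overnight bedroom recording into

1. a sequence of detected *explosive cough sounds* (the countable acoustic
   unit: the initial burst phase of a cough),
2. *cough epochs* — maximal groups of two or more coughs whose consecutive
   gaps are all shorter than 2 seconds, and
3. a *sex assignment* for cough sounds, so that coughs of the intended
   subject can be separated from a differently-sexed bed partner.

Because real overnight recordings contain protected health information and
are not distributable, the package also ships a synthetic night-audio
generator that plants ground-truth coughs and confounder sounds into a
pink-noise background, so every stage can be exercised and validated end to
end on a desk-scale machine.

## Stage 1: silence filtering

Overnight audio is mostly quiet. A Sound-Finder-style amplitude filter
(`mark_silence()`) scans the recording in 10 ms RMS frames and labels
contiguous stretches below −26 dBFS lasting at least 1 s as `silence`; the
complement is `sound`. Only sound regions need be scored by the classifier.

During sliding-window scoring (`slide_and_score()`), the per-window decibel
filter uses the window's **peak** amplitude rather than its RMS by default.
A cough is a transient of a few hundred milliseconds inside a 650 ms
analysis window: its energy averaged over the whole window can fall below
−26 dB even when its peak is 20 dB above the threshold. The peak statistic
keeps every window that touches a supra-threshold transient; `measure =
"rms"` is available for the conventional behavior.

## Stage 2: window classification

### Features

Each 650 ms window is represented as a log-Mel spectrogram with 80 Mel bands
and 122 STFT frames (frame length 1024, hop 110, Hann window, no center
padding). Two conventions deserve note:

* the window length in samples is `floor(0.650 * 22050 + 0.5) = 14333`
  (round-half-up, not banker's rounding), and
* the trailing partial STFT frame is zero-padded rather than dropped, so the
  frame count is `1 + ceiling((14333 - 1024) / 110) = 122`, matching the
  network's 80 × 122 input map exactly.

### Network and ensemble

A small CNN (`cnn_architecture()`) scores each window: five convolutional
layers with "same" padding and ReLU (kernels 1×7, 7×1, 3×3, 3×3, 3×3), 2×2
ceil-mode max-pooling after the first four, global max-pooling, and a single
sigmoid output. Training (`train_member()`) uses Xavier initialization,
Adam, binary cross-entropy, and dropout 0.5 on the pooled feature vector.
The implementation is pure R: convolutions are im2col patch extraction
followed by one BLAS matrix product, with patch/pool index tables cached per
layer geometry; correctness is anchored by a finite-difference gradient
check in the test suite.

Nighttime audio is overwhelmingly non-cough, and the package confronts this
class imbalance on two axes:

* **Ensemble undersampling.** Noncough windows are split into five
  participant-disjunct folds (`make_disjunct_folds()`; no participant's
  windows appear in two folds), each paired with the full cough set; one CNN
  is trained per fold and the ensemble probability is the arithmetic mean of
  the five member probabilities.
* **Balanced minibatches.** Every gradient step sees exactly half cough and
  half noncough windows (`balanced_batches()`): the majority class is
  consumed in shuffled chunks, the minority class resampled with
  replacement.

### Training windows

The training corpus (`synth_window_corpus()`) cuts labeled windows out of
per-participant synthetic audio, and its geometry is chosen to match how the
classifier is later *deployed* — sliding over a night at a 65 ms stride:

* **Jittered positives.** Each cough window is centered on the cough's peak
  sample plus a uniform offset in ±0.10 s, so the network tolerates the
  alignments the sliding window actually produces instead of only
  perfectly-centered coughs.
* **Shoulder negatives.** Each cough also contributes two noncough-labeled
  windows centered ±0.33 s from its peak. These teach the network to score
  *partially overlapping* windows low, which keeps the above-threshold
  response to a single cough to a short run of strides. Without them the
  response run can exceed the rule-3 run-length limit (below) and a single
  cough is double-counted.

The decision threshold *t* is not fixed at 0.5 but tuned on validation data
over the grid [0.5, 1) in steps of 0.01, maximizing the Matthews correlation
coefficient (`tune_threshold()`); ties resolve to the smallest threshold.

### Desk-scale defaults

The published architecture widths (16/32/32/64/64) are available, and
`cnn_architecture(desk = TRUE)` selects reduced widths (8/12/12/16/16) that
train in minutes on one CPU. The package's own experiments and acceptance
checks run at this desk scale by design; it is a package choice, not an
external requirement.

## Stage 3: segmentation and epochs

Windows slide with a 65 ms stride, producing a probability series. Three
postprocessing rules (`postprocess()`) convert it to cough detections:

1. a maximal run of 2–8 consecutive above-threshold probabilities yields one
   cough at the center of the run's covered time span;
2. an isolated single above-threshold probability `p[i]` yields a cough only
   when `mean(p[i], p[i+1]) > 0.9`;
3. a run longer than 8 yields exactly two coughs (centers of its halves).

Silent windows carry probability zero and therefore break runs. Epochs
follow from the 2-second rule (`derive_epochs()`), with strict inequality
and singletons excluded.

Because the postprocessing rules were derived on validation data in the
source methodology, the package mirrors that practice for the deployment
threshold: `tune_segmentation_threshold()` calibrates *t* directly against
annotated cough counts on held-out validation nights, returning the midpoint
of the longest plateau of count-optimal thresholds. The window-level MCC
grid search often ties across a wide range; where in that range *t* falls
controls how many neighboring windows join each detection run, which rule 3
would otherwise split into spurious double counts.

The validation nights used for this calibration are simulated *event-dense*
(cough-epoch and isolated-cough rates several times the evaluation default,
confounders likewise): each calibration night then carries many more
count-relevant events, so the count-optimal plateau is localized from a few
night-hours of validation audio. Evaluation nights are left at the default
sparse rates.

Detections are matched to annotations greedily, one-to-one, in time order,
a prediction matching the first unmatched annotated cough whose interval
dilated by ±0.5 s contains it (`match_detections()`).

## Stage 4: sex assignment

Each cough (or concatenated cough epoch) is represented by a 41 × F feature
matrix (`extract_sex_features()`): 20 MFCCs (4096-sample frames, 4096-point
FFT, hop 256, 40 Mel bands, orthonormal DCT-II, including coefficient 0),
their first time-derivatives (centered difference with edge replication),
and the first derivative of the per-frame zero-crossing rate. The frame
count here follows the conventional floor rule, `F = 1 + floor((N - 4096) /
256)`: unlike the CNN input, no fixed output geometry forces padding.

One diagonal-covariance Gaussian mixture model with K = 30 components is
fitted per sex (`fit_gmm()`) by EM from k-means seedings, best of 3
initializations, 200 iterations, with variances floored at 1e-6. A signal is
assigned the sex whose model gives the larger total log-likelihood summed
over frames (`classify_sex()`); exact ties return female with a `tie` flag.
Epoch-level classification simply concatenates the member coughs, giving the
likelihood more frames to accumulate evidence — epoch-level accuracy is
expected to be at least cough-level accuracy.

## Evaluation

`confusion_metrics()` reports sensitivity, specificity, accuracy, MCC, PPV
and NPV, with `NA` (never silently 0) when a denominator is zero.
`roc_pr_curves()` traces ROC and precision–recall curves over all distinct
score thresholds with ties grouped, and integrates areas by the trapezoid
rule. `bland_altman()` compares automated and annotated per-night counts:
mean difference and mean ± 1.96 · SD limits of agreement.

## The synthetic night generator

`synth_night()` emulates the statistical structure of an overnight
recording rather than its acoustics:

* a pink-noise background (Kellet's filter cascade) at −50 dBFS by default —
  below the silence threshold, so pure background reads as silence;
* synthetic coughs: a broadband burst with 5 ms attack and ~150 ms
  exponential decay plus a voiced harmonic tail (5 harmonics, amplitudes
  1/h) at a sex-typical fundamental: 85–180 Hz male, 165–255 Hz female,
  with the 165–180 Hz overlap excluded by default so synthetic ground truth
  is unambiguous;
* noncough confounders from five spectrally distinct archetypes: snore,
  tone, chirp, thump, babble;
* cough epochs with 2–5 coughs and intra-epoch gaps drawn from
  U(0.3, 1.0) s — safely under the 2 s rule — and all event blocks
  separated by at least 3 s, so planted epoch structure is exact.

The generator's purpose is pipeline validation: its events are
well-separated, its classes separable, and background stationary. Results on
it bound nothing about real bedrooms; they verify that the machinery —
features, training, thresholding, postprocessing, counting, matching,
assignment — is internally correct.

## Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state. `run_end_to_end()` fans one global seed out to per-stage seeds by
fixed offsets, writes per-night counts (CSV), metrics and a seed manifest
(JSON), and is deterministic given its configuration.
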