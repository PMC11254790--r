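---
title: "Single-heartbeat ECG identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-heartbeat ECG identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

heartbeatID identifies enrolled subjects from single R-R heartbeats of
single-lead ECG. This vignette is the package's account of the underlying
science: the processing model and its assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design decisions taken where the problem left them open.

## The identification problem

Closed-set identification assigns each probe beat to one of the enrolled
subjects; there is no rejection of unknowns. The discriminative signal is
inter-individual P-QRS-T morphology — wave amplitudes, widths and timing
relative to the R peak — which is stable within a subject over the time
scales considered here. The unit of classification is one complete cardiac
cycle clipped between two successive R peaks (an R-R segment), rather than
a fixed window centered on the R peak: the R-R segment covers the full
systolic and diastolic phases regardless of heart rate.

## Preprocessing

Two operations standardize heterogeneous sources:

* **Resampling to 250 Hz** (`preprocessConfig(targetFs = 250)`). Source
  databases run anywhere from 125 to 500 Hz; one common rate makes window
  lengths and the 150-sample beat meaningful across sources. Resampling is
  rational-factor polyphase: upsample by `p`, apply a linear-phase
  windowed-sinc FIR low-pass at the narrower Nyquist frequency, compensate
  its exact integer group delay, and keep every `q`-th sample. The exact
  delay compensation matters because downstream ground-truth comparisons
  and fiducial clipping assume sample-accurate alignment; conversions such
  as 128 to 250 Hz and 500 to 250 Hz are exact rational ratios with no
  spectral imaging.
* **Band-pass 0.6–40 Hz, 3rd-order Butterworth** (`lowCut`, `highCut`,
  `order`). The band removes baseline wander (breathing and movement,
  below ~0.5 Hz) and attenuates power-line interference and EMG noise
  above 40 Hz while preserving QRS energy. By default the filter is
  applied forward and backward (`zeroPhase = TRUE`), so the effective
  magnitude response is |H(f)|² and there is no group delay. Phase
  handling is a genuinely open choice — a causal implementation is equally
  defensible for streaming use — but zero-phase keeps beat morphology
  aligned with the detected fiducials, which matters when beats are
  clipped at fixed sample offsets; the causal mode remains available via
  the flag.

## R-peak detection

`detectRPeaks` implements the classic Pan–Tompkins cascade with its 1985
constants, scaled by the sampling rate: 5–15 Hz band-pass, five-point
derivative, pointwise squaring, 150 ms moving-window integration, adaptive
dual thresholds on the integrated and band-passed signals with running
signal/noise peak estimates, a 200 ms refractory period, search-back with
halved thresholds when no QRS is found within 166% of the running RR
average, and T-wave rejection by slope comparison for candidates within
360 ms of the previous QRS.

One numerical detail is worth recording: the integrated signal around a
QRS is a plateau roughly as wide as the integration window, so the
location of its local maximum can wander by tens of milliseconds. Each
accepted candidate is therefore first anchored to the maximum of the
5–15 Hz band-passed signal within ±80 ms, then refined to the maximum of
the input signal within ±40 ms. Without the anchoring step the ±40 ms
refinement window can miss the R peak entirely.

Detection assumes a dominant positive R deflection, which holds for the
synthetic generator and for typical lead-I/MLII recordings; inverted-QRS
leads would need a polarity flip before detection.

## Rigid RR-length thresholding

From all inter-peak lengths Δxᵢ = xᵢ − xᵢ₋₁ of a record, eight reference
lengths in the normal range are selected; their mean μ and *population*
standard deviation σ (divisor N = 8) define the retention band
[μ − σ, μ + σ]. Only segments with RR inside the band are kept; equality
is retained, because only values strictly below th1 or strictly above th2
are deemed aberrant. Retained segments are interpolated onto 150 samples
over normalized time (linear by default: exact on piecewise-linear data
and free of ringing; cubic available). Segments use the half-open
convention [xᵢ₋₁, xᵢ), so consecutive beats tile the record without
duplicating the shared R sample. Thresholds are computed per record and
never pooled across subjects — the statistics are defined over one
record's peaks.

The original procedure selected the eight "normal" reference RR lengths by
manual observation. Automation has to commit to a rule; the default here
is **median-nearest**: the eight values with the smallest |Δx − median|,
ties broken by earliest occurrence. The median is robust to exactly the
artifacts the rule must exclude. The consequence to understand is that on
records with continuous RR variability the eight median-nearest values
cluster tightly, σ collapses toward zero, and the band retains only beats
whose RR matches the record's modal RR at sample resolution. The rule is
therefore strict on high-variability records — a property inherited from
the μ ± σ band itself, which retains at most the central ~68% of a
normally distributed RR population even when the reference spread matches
the population spread. A `first-k` rule is provided for sensitivity
analysis.

## The synthetic generator

Every downstream stage is tested against records with known ground truth.
A subject is a sum-of-five-Gaussians template (P, Q, R, S, T), each wave
with a center offset relative to the R peak (ms), a signed amplitude (mV)
and a Gaussian width (ms), drawn uniformly from physiologically ordered
ranges (e.g. R amplitude 0.8–1.6 mV, T center 200–300 ms). RR intervals
follow a truncated normal law (mean, SDNN, floor). Noise comprises
exactly the classes the band-pass is meant to remove: sinusoidal baseline
wander (default 0.1 mV at 0.25 Hz), power-line interference (0.05 mV at
50 Hz) and broadband white noise (0.02 mV) — levels chosen to be visible
in the raw trace and clearly attenuated by the 0.6–40 Hz band. Records
are generated at 500 Hz by default so the 250 Hz standardization stage is
genuinely exercised. `injectArtifacts` perturbs chosen inter-beat
intervals — premature beats (halved RR), missed beats (doubled RR) or
noise bursts — so the thresholding stage has something to reject, and
reports which intervals it touched.

For multi-subject cohorts (`generateCohort`), per-subject mean RR is drawn
from a 4 ms grid between 700 and 1000 ms (one sample at 250 Hz) with zero
sinus variability. This emulates highly regular resting rhythm and is a
deliberate simplification: with the median-nearest reference rule, regular
rhythm is the regime in which the rigid band retains the regular beats and
rejects the injected artifacts cleanly. Intra-subject variation then comes
from measurement noise, filtering residue and artifacts.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: arrhythmic morphology (ectopic beats here
are early, not morphologically abnormal), realistic heart-rate-variability
spectra, electrode-motion transients, multi-session electrode-placement
drift, inverted or biphasic QRS, and multi-lead redundancy. On real
recordings with ordinary sinus variability the thresholding stage will
discard a substantially larger fraction of beats than it does on these
cohorts.

## Class balancing

Enrollment data are imbalanced (one subject may contribute hundreds of
beats, another a handful). `balanceDataset` equalizes classes to a target
— the rounded mean of class sizes or their maximum — using original SMOTE
for minorities (each synthetic row is x + λ(x_nn − x) with λ ~ U[0,1] and
x_nn one of the k = 5 nearest same-class neighbors under Euclidean
distance on the 150-sample vectors) and uniform down-sampling without
replacement for majorities, to an exact 1:1 ratio. All original minority
rows are retained, labels never cross classes, and every synthetic row's
provenance (seed row, neighbor, λ) is recorded so the interpolation can be
replayed and verified. A class of size one cannot be interpolated and is
an error rather than a silent duplication.

Where balancing happens is a protocol decision with leakage consequences:
balancing the whole dataset before splitting lets SMOTE interpolants of
test beats reach training. The default scope is therefore `train_only`
(split first, balance the training partition only); `whole_dataset` is
retained because it reproduces the protocol under which near-perfect
published scores are attainable, and the documentation flags the risk.

## The classifier

The network is deliberately small: conv(16 kernels, size 3) + ReLU,
max-pool(2), conv(32, 3) + ReLU, max-pool(2), flatten, dense(100) + ReLU,
dropout(0.2), dense softmax. With valid padding and 150-sample input the
feature lengths are 148 → 74 → 72 → 36, the flattened width 1152, and the
trainable-parameter count 64 + 1,568 + 115,300 + 101·N for N classes
(118,750 at N = 18). Padding is not dictated by the architecture
description; `valid` is the default and `same` is selectable.

Training follows a fixed recipe: Adam at learning rate 0.001, batch size
32, categorical cross-entropy, at most 500 epochs. Early stopping details
are open; the package fixes validation-loss monitoring with patience 20
and best-weights restoration, standard practice consistent with "early
stopping" as the named regularizer. Beats are fed in mV without per-beat
normalization by default (a per-beat z-score flag exists for robustness
studies). Label order is the sorted set of training subject ids, fixed
before any split; a validation or test label outside it is an error, per
the closed-set contract. Prediction is the softmax argmax with ties
resolved toward the lowest class index.

Because no deep-learning framework is part of the package's dependency
set, forward/backward propagation (im2col convolution, max-pool argmax
routing, inverted dropout) and Adam are implemented in R with matrix
multiplication. Glorot-uniform initialization, shuffling and dropout all
draw from one seeded RNG stream, so training is bit-reproducible on a
single thread.

## Evaluation

The confusion matrix has true classes in rows and predictions in columns.
Overall accuracy is the trace over the total — the multi-class "correct /
all" reading; the per-class binary accuracy (TP+TN)/total is also
computed per class for completeness. Precision TP/(TP+FP), sensitivity
TP/(TP+FN) and their harmonic mean F1 are computed one-vs-rest per class
and macro-averaged (unweighted), so rare subjects count as much as
frequent ones; weighted averaging is never used. Any 0/0 is defined as 0
and flagged with a warning.

## Experimental protocols

Two scenarios mirror the two ways the data can be used:

* **Imbalanced**: no balancing; 20% of beats held out once
  (stratified), the remaining 80% partitioned into five stratified folds;
  each fold serves once as validation while the other four train, and each
  fitted model is evaluated on the held-out test beats; per-fold reports
  and their mean ± sd are returned. Combining a held-out test fraction
  with 5-fold cross-validation admits several readings; this one (test
  held out once, CV over the remainder, evaluation per fold) keeps every
  beat's fold membership and the test set disjoint.
* **Balanced**: 60:20:20 stratified split, SMOTE balancing per the scope
  above, one training run, one report.

Stratification by subject is not optional in spirit: a closed-set
identifier must see every class in every partition, and splits error out
on classes with fewer than three beats.

## Problem sizes and numerical tolerances

The test suite and the acceptance script size their simulations for a
single CPU: identification uses a 20-subject cohort with 30–200 beats per
subject (balanced/max, train-only scope); detector quality uses twenty
one-minute records with per-subject SDNN of 20–50 ms; thresholding
selectivity uses ten one-minute regular-rhythm records with four injected
artifacts each. CSV round-trips are verified to 1e-6 mV (text
serialization uses at least six significant digits); filter linearity to
1e-9; SMOTE replay to 1e-9; metric identities to 1e-12. Detection
tolerance is ±40 ms (±10 samples at 250 Hz), the same window used for the
final fiducial refinement.

## Known limitations

* Open-set operation (rejecting unknown probes) is out of scope; softmax
  scores are not calibrated for rejection thresholds.
* The rigid μ ± σ band discards many genuine beats on high-variability
  records, and the automated reference-RR selection makes it stricter
  still (see above); recall of enrolled beats, not beat-level coverage,
  is the design goal.
* The WFDB reader covers headers plus format-16 signals with gain/baseline
  conversion — sufficient for interchange and round-trip testing, not a
  complete WFDB implementation (formats 212/80, multi-segment records and
  annotations are not supported).
* Training the pure-R network is practical at the package's cohort sizes
  (thousands of beats, a few hundred classes at most), not at
  production-database scale.
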