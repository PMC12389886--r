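---
title: "Pain-state classification and maxAP estimation from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pain-state classification and maxAP estimation from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painflex)
```

## The problem

After a fracture around the knee, intra-articular adhesions stiffen the
joint and restrict its range of motion. Mobility training flexes the knee
to the *maximum angle position* (maxAP) — the angle at which the patient's
pain reaches level 3 on the numerical rating scale — far enough to stretch
the adhesions, but no further. The maxAP changes from session to session
and is normally judged by a therapist from the patient's verbal report. A
rehabilitation robot has no access to that report. `painflex` implements
the signal-processing and learning pipeline that lets a robot infer the
pain state, and hence the maxAP, from the patient's own muscle activity:
four channels of surface EMG (the knee extensors MRF and MVM, the flexors
MBF-CL and MS, 2000 Hz), processed strictly causally as a real-time system
would.

The pipeline's premise is physiological: as flexion-induced pain rises,
patients unconsciously contract the extensors to resist further flexion,
so the EMG amplitude rises and plateaus, while spectral content shifts
slightly downward. Each training trial has a flexion phase (trial start to
the pain mark — windows labeled *painless*) and a hold phase at the maxAP
(pain mark to extension — labeled *pain*), turning maxAP detection into a
binary classification problem on sliding windows.

## Preprocessing

Recordings are band-pass filtered 20–450 Hz and notch filtered at 50 Hz
with zero-phase (forward–backward) filters, then cut into trials at the
`(start, pain, end)` marker triples; everything outside a trial is
discarded. The source description fixes the corner frequencies but not
the filter orders; we use a 4th-order Butterworth band-pass and a
2nd-order IIR notch with Q = 30, standard choices in surface-EMG work,
and verify their magnitude response analytically in the tests. Marker
times are snapped to the nearest sample, ties rounding down. Zero-phase
filtering means no group delay: the pain mark stays aligned with the
signal, which matters because the phase boundary is also the label
boundary.

## Window features

Features are extracted in 250 ms windows advanced by 125 ms (500 and 250
samples at 2000 Hz). Per channel and window, 33 values:

* **Amplitude**: RMS, mean absolute value, unbiased variance, waveform
  length (summed absolute successive differences).
* **Waveform frequency**: zero crossings and slope-sign changes, both
  guarded by an amplitude threshold of 0.005 mV so noise-level wiggles do
  not count. The source formulas write the guard without absolute values;
  read literally that would make the counts depend on sign order, so we
  apply the guard to absolute differences (the standard Hudgins
  definition) and expose `eps_abs = FALSE` for the literal form.
* **Spectrum**: mean and median frequency of the one-sided raw
  periodogram of the unwindowed segment, bins at multiples of
  `fs/N` = 4 Hz. The spectral estimator was not specified; the raw
  periodogram matches the stated `P_j, j = 1..N/2` indexing. The median
  frequency tie-break takes the smallest bin reaching half the total
  power. An all-zero window has no defined spectral centroid and yields
  flagged `NA`s.
* **Wavelet packets**: a full 3-level db4 wavelet-packet tree gives 8
  terminal sub-bands (125 Hz wide), reported frequency-ascending; per
  band we keep RMS, variance and energy. We implement the periodized
  orthonormal filter bank directly and zero-pad each window to the next
  multiple of `2^level` first: 500 is not divisible by 8, and periodizing
  an odd-length node (as common library implementations do, by padding)
  silently breaks energy conservation. With the zero-pad the transform is
  exactly orthogonal, so the 8 sub-band energies sum to the window energy
  to machine precision — a property the test suite asserts at 1e-9.
  Frequency ordering swaps the children of every high-pass branch, since
  downsampling mirrors that band's spectrum.
* **Complexity**: sample entropy with embedding dimension `m = 2`,
  Chebyshev distance, self-matches excluded, tolerance `r` = 0.2 × the
  window's sample standard deviation. The source leaves the scope of the
  standard deviation ambiguous (window, trial or recording); we use the
  per-window value, which keeps the feature self-contained and
  amplitude-invariant. When no template pair matches at length `m + 1`
  the statistic diverges; we return the maximum resolvable value
  `-ln(2/((N-m-1)(N-m)))` with a `capped` flag rather than an infinity.

A window straddling the pain mark is labeled *pain* only when it lies
entirely inside the hold phase. This is the reading consistent with the
window-count arithmetic of the phase-labeling contract (a 10 s flexion +
3 s hold trial yields 103 windows of which 23 are pain), it is causal,
and it is conservative: ambiguous windows count as painless. The
alternative end-time rule is available as `label_rule = "end"`.

## Classifiers and the double cross-validation

**Cost-sensitive SVM.** A linear soft-margin SVM in which slack on
pain-class samples (+1) costs `R*C` and painless slack costs `C`, solved
by LIBSVM via `e1071` with per-class weights. Because margin methods are
scale-sensitive and the source does not mention scaling, features are
z-scored with training-fold statistics by default (`scale = FALSE`
restores the raw behavior); the statistics travel with the model so test
folds are transformed, never re-estimated.

**Tuning.** For each subject the 8 trials are randomly split into 4 sets
of 2; each set is once the test set while the other three feed an inner
rotation: two sets fit the model, the third validates, rotating three
times. Each `(R, C)` pair — powers of two — is scored by
`T = 0.2 Acc_v + 0.2 Acc_o + 0.3 Pre_v + 0.3 Rec_v` averaged over the
rotations, and the argmax is refitted on all training windows. `Acc_o`
is taken as the training accuracy of the two optimization sets — the
procedure description leaves this open, and the training-accuracy reading
is the one that requires no extra data. Ties break toward the smallest
`C`, then the smallest `R` (stronger regularization, weaker asymmetry).
An inner fold whose validation set lacks one class has no defined
precision or recall; such folds are dropped from the T average with the
remaining rotations still counted. Because all splitting is at trial
level, no trial ever contributes windows to both sides of any fit.

**Random forest.** A probability forest (`ranger`) tuned over the number
of trees `N_T` and minimum leaf size `N_L` by a seeded Gaussian-process /
expected-improvement search over the integer box, with the same
inner-rotation mean T as the objective. Defaults: `N_T` in [10, 200],
`N_L` in [1, 50]. The decision score is `P(pain) - 1/2`.

Two grid presets are provided. `classifier_spec("full")` spans every
integer exponent in `2^-20 .. 2^20` with 30 optimizer iterations;
`classifier_spec("desk")` — the default, used throughout the tests and
the acceptance script — uses exponents `-8, -4, 0, 4, 8` and 10
iterations, which keeps a full seven-subject, two-classifier evaluation
within minutes on one core at an immaterial cost in tuned performance on
the synthetic cohorts.

## Pseudo-online detection and maxAP estimation

At run time each window is scored independently in time order, so the
decision stream is causal by construction. The raw labels are smoothed
with a causal majority vote over the last five decisions (~0.75 s),
which removes the sporadic isolated flips without using future windows;
the smoothing operator was not specified at the source, and a centered
retrospective mode is provided for comparison. Ties in a truncated
prefix vote go to *painless*, so smoothing never invents a detection.

The maxAP estimate is the joint angle, linearly interpolated, at the end
time of the first smoothed *pain* window. Detections at or before the
pain mark are *early* and carry the signed bias
`true maxAP - detected angle` (positive = early = the safe side — an
under-shoot merely under-trains, an over-shoot risks injury). Detections
during the hold are flagged *delayed* and carry no bias: the robot is
already holding at the maxAP, so the angle difference is zero by
construction and says nothing about estimation quality. Cohort summaries
therefore average bias over early trials only (an inclusive mean, with
delayed trials entering at zero, is reported alongside), and the early
fraction counts `early / (early + delayed)`.

## Feature statistics across subjects

For therapist-administered (Experiment-I-style) data the package
reproduces the group-level feature analysis: features are z-scored per
subject (min–max optional; the normalization at the source is unstated,
and z-scoring is what makes per-state mean differences comparable across
subjects), averaged per state, and compared with two-sided paired
t-tests per feature, starred at 0.05/0.01/0.001. No multiple-testing
correction is applied to the stars, mirroring the per-feature
convention; a Holm-adjusted column is emitted for users who want it.

## The synthetic generator

No patient recordings are distributable, so the package ships a seeded
generator emulating the statistical structure the pipeline relies on:

* joint angle ramping linearly (10° to 70° over 10 s by default, ~6°/s —
  slow passive flexion) then holding ~5 s, the robot protocol;
* a latent pain level tied deterministically to the angle,
  `p = 3 clip((angle - onset)/(maxAP - onset), 0, 1)`, reaching the
  clinical level 3 exactly at the maxAP (onset 40° by default, jittered
  ±5° per subject — per subject, not per trial, because the robot's
  preset angle makes the threshold a subject property);
* per-channel EMG as band-limited (20–450 Hz) Gaussian noise modulated
  by the envelope `baseline + gain * drive^2`, with extensor gains three
  times the flexor gains, per-subject log-normal gain jitter (sd 0.15),
  per-trial log-normal amplitude jitter (sd 0.10) and a slow (< 1 Hz)
  envelope wobble (sd 0.05) so that trials are neither identical nor
  trivially separable;
* the envelope drive saturating at 85% of the pain rise
  (`envelope_sat`): patients' protective contraction plateaus shortly
  before the joint reaches the maxAP (the muscular reaction precedes the
  verbal report), which is precisely what makes early detection of the
  transition possible and early detections dominate;
* a pain-coupled spectral shift moving 20% of carrier power from the
  150–450 Hz band to the 20–150 Hz band at full pain, lowering the
  median frequency in the hold phase;
* 50 Hz mains interference (0.005 mV) for the notch filter to remove.

`healthy_mode()` reduces the pain gains to 10% and disables the spectral
shift, emulating the much weaker, direction-inconsistent activation of
healthy controls. Defaults were fixed once, to sit comfortably above the
pipeline's recovery threshold without saturating it: on the default
seven-subject cohort the double cross-validation reaches ~88–94% mean
accuracy with visible false positives and negatives, early fractions
above 80% and positive mean biases of a few degrees.

What the generator does *not* model: motor-unit dynamics and discharge
rates (the carrier is filtered noise, not a physiological EMG model),
movement artifacts, electrode lift, co-contraction strategies, or
patients whose pain response is non-monotone in angle. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
assumed structure when it is present — not that the structure holds in
any particular patient.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full evaluation on a
seven-subject, eight-trial synthetic cohort (≈950 windows of 132
features per subject) with the desk preset; the type-I calibration study
uses 200 scaled-down zero-effect cohorts (400 Hz, three 3 s trials, five
subjects) — sizes chosen so that a complete run stays a desk-scale
computation. Other numerical decisions collected in one place: marker
snapping ties round down; the window count per trial is
`floor((L - N)/S) + 1`; degenerate (single-class) inner validation folds
drop out of the T average; zero-variance features are left unscaled by
the per-subject normalization and skipped by the SVM z-scoring
(unit scale); a paired t-test with identically zero differences is
flagged degenerate rather than returning `NaN`; and every stochastic
step (fold assignment, forest bootstraps, the Bayesian optimizer, the
generator) draws its seed deterministically from one master seed.

## Limitations

The package evaluates pseudo-online performance on recorded or simulated
trials; it does not implement closed-loop robot control, interaction-force
fusion, or multi-level (0–3) pain grading — the task is deliberately the
binary level-3 threshold that defines the maxAP. Reported patient-level
numbers in the literature stem from recordings that are not publicly
deposited, so the package's quantitative claims about real data are
limited to what can be recomputed from published per-subject tables
(shipped in `inst/extdata/`); everything else is validated analytically,
against brute-force oracles, and on the synthetic cohorts described
above.
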