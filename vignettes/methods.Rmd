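---
title: "Methods: wavelet-feature EEG screening for dyslexia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-feature EEG screening for dyslexia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Dyslexia screening from task-evoked EEG is framed here as a binary
classification problem at the *epoch* level: a multichannel scalp recording
(16 retained 10–20 channels — Fp1, Fp2, F3, F4, F7, F8, T3, T4, T5, T6, P3,
P4, O1, O2, C3, C4 — at a nominal 256 Hz, midline electrodes excluded) is cut
into non-overlapping 10-s epochs, each epoch is summarised by a vector of
wavelet-domain statistics, and a classifier predicts the subject's class
(dyslexic = 1) for every epoch. With 51 subjects (26/25) recorded for 340 s
each, the reference cohort structure yields 34 epochs per subject and
1,734 epochs in total (884/850 per class).

`eegscreen` implements the complete chain — EDF input, preprocessing,
epoching, db4 level-6 discrete wavelet decomposition, ten statistical
descriptors per band and channel, mRMR and ReliefF feature ranking,
neural-network and classical classifiers under stratified 10-fold
cross-validation, and effect-size/FDR feature screening — plus a synthetic
cohort generator that stands in for clinical data, which is typically
private in this domain.

## Preprocessing

Three stages, in a fixed order that is our serialization choice (band-pass →
moving average → ICA):

* **Band-pass, 0.1–70 Hz.** A 4th-order Butterworth high-pass at 0.1 Hz
  followed by a 4th-order low-pass at 70 Hz, each applied forward–backward
  (zero phase). The filters run as cascaded second-order sections: at 256 Hz
  the 0.1 Hz corner has a normalized frequency of 8e-4, and the expanded
  order-4 transfer polynomial is numerically unstable there (we observed
  1e16-scale blow-ups with the expanded form; the SOS cascade matches a
  reference implementation to ~1e-12). `bandpass_gain()` exposes the exact
  two-pass magnitude response so tests compare measured attenuation against
  the analytic value rather than a folklore number.
* **Moving average, window 9 samples** (~35 ms at 256 Hz), centred, with
  symmetric reflection padding. This is a mild low-pass on top of the
  band-pass.
* **ICA artifact removal.** Fixed-point (logcosh) ICA with *deflation*,
  seeded for reproducibility. Deflation rather than the symmetric update is
  a deliberate choice: EEG-like data can contain a near-Gaussian subspace in
  which the symmetric iteration has no stable fixed point and oscillates
  indefinitely (our synthetic oscillations are Gaussian by construction, the
  worst case). Non-Gaussian components — artifacts — converge individually;
  the Gaussian remainder is completed with an arbitrary orthonormal basis,
  which is statistically equivalent and harmless for reconstruction. Visual
  component screening is replaced by two thresholded criteria
  (`artifact_criteria()`): a component is *ocular* if its time course
  correlates (|r| > 0.7) with a 0.5–4 Hz frontal proxy (mean of Fp1/Fp2),
  and *EMG* if more than 60% of its spectral power lies in 30–70 Hz and its
  mixing weights are posterior-dominant. At most 4 components are removed by
  default; setting the cap to 0 turns the step into a pure report.

## Wavelet decomposition and the band-mapping duality

Each 2,560-sample epoch-channel signal is decomposed with the Daubechies-4
wavelet at level 6. We use the *periodized* DWT, which is exactly
orthogonal: reconstruction and Parseval energy conservation hold to machine
precision (the package's acceptance bounds are 1e-8 and 1e-6 relative
error). Symmetric extension was considered and rejected: it is redundant
(extra boundary coefficients) and violates energy conservation at
O(filter length / epoch length), which would break the stated Parseval
bound. At 2,560 samples the coefficient set sizes are A6/D6: 40, D5: 80,
D4: 160, D3: 320, D2: 640, D1: 1,280.

Two coefficient-to-band mappings are shipped because the conventional
level-to-band table used in this literature corresponds to a 512 Hz dyadic
ladder, while the recordings are 256 Hz:

| band  | nominal Hz | `table3_literal` | `frequency_consistent` @256 Hz |
|-------|-----------|------------------|-------------------------------|
| delta | 0.5–4     | A6 (0–2 Hz)      | A6 + D6 (0–4 Hz)              |
| theta | 4–8       | D6 (2–4 Hz)      | D5 (4–8 Hz)                   |
| alpha | 8–13      | D5 (4–8 Hz)      | D4 (8–16 Hz)                  |
| beta  | 13–30     | D4 (8–16 Hz)     | D3 (16–32 Hz)                 |
| gamma | 30–60     | D3 (16–32 Hz)    | D2 (32–64 Hz)                 |

`table3_literal` is the default (faithful to the published procedure);
`frequency_consistent` assigns each band the dyadic set(s) actually covering
its Hz range and is used by the spectral sanity and effect-recovery tests —
a 6 Hz probe concentrates its energy in the theta-assigned set only under
this mode. Which mapping a given study actually computed at 256 Hz is
usually undecidable from the text; shipping both makes the choice explicit
and logged.

## Features

Ten descriptors per band-channel coefficient vector, in fixed order: mean,
median, variance, standard deviation, skewness, kurtosis (non-excess:
Gaussian → 3), interquartile range (linear-interpolation quartiles,
R type 7), mean absolute deviation about the mean, RMS, and Shannon
entropy. All moments use population (1/N) normalisation, matching the
printed formulas of this literature; skewness and kurtosis are defined as 0
when the variance is 0. The entropy is the base-2 Shannon entropy of an
equal-width 16-bin histogram spanning [min(x), max(x)] — bin count and base
are conventions we fixed (and log) because they are rarely stated; entropy
is then invariant under positive rescaling of the coefficients, like
skewness and kurtosis. One upstream formula prints mean absolute deviation
degenerately (|xi − xi|); we implement the standard deviation-about-the-mean
reading of the prose.

Columns are ordered bands × channels × statistics and named
`band.channel.statistic`, giving 160 features per band, 640 for the fused
4-band set and 800 with gamma included.

## Feature selection

* **mRMR** ranks greedily by mutual information: the first feature maximizes
  I(x; C); each next feature maximizes I(x; C) − mean I(x; selected). The
  combination of relevance and redundancy is not dictated by the usual
  formulas (they specify max-relevance and min-redundancy separately); we
  default to the difference (MID) scheme with the quotient available by
  flag. MI uses equal-frequency 10-bin discretization (features with ≤ 10
  distinct values are used as categories directly — naive quantile binning
  silently collapses binary features into one bin). Ties break to the lower
  feature index, so rankings are deterministic.
* **ReliefF** weights features by how well they separate each instance from
  its k nearest misses versus its k nearest hits (Manhattan distance on
  range-scaled features, k = 10 by default). With `m = "all"` (default)
  every instance is visited once and the result is fully deterministic;
  weights then lie in [−1, 1]. The binary-class prior factor is exactly 1.

Both selectors are implemented from scratch and verified against exhaustive
brute-force oracles in the test suite.

## Classifiers and validation

The bespoke models are two feed-forward networks: a deep network (four
blocks of dense → batch-norm → ReLU → dropout 0.5, widths 256-128-64-32 by
default) and a shallow one (three blocks, 128-64-32), each ending in a
dense layer and 2-way softmax. Widths are our defaults — the source
literature specifies block counts, batch size 16, Nadam, learning rate
0.001 and 30 epochs, but not widths — and are recorded in every report.
Training holds out a stratified 10% of each training fold for early
stopping (patience 5 on validation loss) and standardizes inputs per fold.
The optimizer, batch-norm and backpropagation are implemented in plain
matrix algebra (no deep-learning runtime is assumed) and gradient-checked.

Classical baselines are plumbing around standard estimators available in
the environment: LDA/QDA (MASS), ridge-regularized logistic regression
(glmnet), Gaussian naive Bayes and kNN (both trivial, implemented
in-package). Tree, SVM and ensemble variants that appear in the surrounding
literature are not shipped because no corresponding library is available in
the target environment and baseline solvers are explicitly not the
contribution.

Validation is segment-level stratified 10-fold cross-validation: epochs of
one subject may land in both train and test folds, which mirrors the
emulated protocol but flatters generalization to unseen subjects
(intra-subject correlation). `run_cv(..., grouping = "subject")` provides
grouped folds to expose exactly that caveat. Metrics per fold: accuracy,
class-weighted precision/recall/F1 (weighted recall equals accuracy by
construction, which is why those columns match in this literature's result
tables), rank-statistic AUC, sensitivity and specificity; aggregates are
the across-fold average and maximum. Metrics with an empty denominator are
reported as missing, never as 0.

## The synthetic cohort: a stated world

`cohort_config()` defaults describe the emulated study: 26 + 25 subjects,
340 s at 256 Hz (34 × 10 s epochs exactly; the "5.6 min" sometimes printed
for this design does not divide evenly), 16 channels. Each subject is a sum
of:

* per-band oscillations: random-phase spectral noise confined to the band's
  Hz range (equivalent to ideal band-pass-filtered Gaussian noise), base
  RMS amplitudes delta 20, theta 10, alpha 10, beta 5, gamma 3 µV — chosen
  once as plausible pediatric scalp values;
* 1/f background noise (5 µV RMS);
* blink transients (Gaussian pulses, σ = 80 ms, 60 µV, 10/min,
  frontally weighted) and EMG bursts (30–70 Hz, 20 µV, 5/min, posteriorly
  weighted).

Class effects are injected multiplicatively on band amplitude at the
subject level: a dyslexic subject's band amplitude is shifted by
`d × s_tot`, where `s_tot` is the SD of the per-epoch amplitude multiplier
(`epoch_cv = 0.2` by default), so the configured `d` is approximately the
epoch-level Cohen's d realized on amplitude-tracking features (RMS, SD,
MAD, IQR). Default directions follow reports of elevated slow-wave activity
in dyslexic readers (theta +0.8, delta +0.6, alpha −0.3, beta +0.2,
gamma 0); magnitudes are free simulation parameters, not measured values.

Two deliberate calibration choices:

* **`subject_cv` defaults to 0.** Idiosyncratic per-subject band-power
  variability makes epochs within a subject correlated; with 34 epochs per
  subject even a small subject random effect makes epoch-level Welch tests
  strongly anti-conservative, and the null cohort would no longer satisfy
  the FDR ≤ α calibration criterion. The dial exists (and is tested) for
  studying the subject-leakage phenomenon, but the stated null world keeps
  epoch-level tests calibrated.
* **Cross-band leakage attenuates small effects.** Dyadic wavelet filters
  are not brick-wall: a strong theta oscillation leaks into the neighbouring
  D4 set, and with opposite-signed configured effects (theta +, alpha −)
  the leakage partially cancels the weaker alpha effect. Empirically the
  theta effect is recovered essentially unattenuated (configured 1.0,
  recovered ≈ 1.0 at n = 1,734), while alpha/beta effects of magnitude
  0.2–0.3 shrink towards 0.05–0.1. This is physics of the representation,
  not a generator defect; the recovery acceptance criterion is therefore
  asserted on theta, and the per-band evaluation ordering
  (delta/theta above alpha/beta) remains as configured.

What a green test does **not** establish: the generator has no head model,
no task-locked event structure, no non-stationarities beyond per-epoch
amplitude modulation, and Gaussian oscillations (so no genuine higher-order
statistics for ICA beyond the artifact transients). Classification results
on it say nothing about clinical accuracy; they verify the pipeline's
mechanics, calibration and recoverability.

## Numerical choices and degenerate inputs

* EDF I/O is classic EDF, one 1-s record per signal, 16-bit samples with a
  symmetric per-channel physical range; round-trip error is bounded by
  range/2^15. Files with per-channel sampling rates are rejected rather
  than resampled. Labels survive a round trip via the header
  identification fields.
* filtfilt uses odd-reflection padding with steady-state initial
  conditions (the standard scipy construction); tests that probe the
  response of the 0.1 Hz high-pass do so by projection at the probe
  frequency because its edge transient decays over thousands of samples.
* Ranking tie-breaks are always "lower feature index first"; fold
  assignment deals shuffled class members round-robin, so per-fold class
  counts differ by at most one.
* Zero-variance features: d = 0, p = 1, flagged `degenerate` in
  `feature_group_stats()`; constant features get ReliefF weight exactly 0;
  constant vectors get entropy 0 and skewness/kurtosis 0.
* All randomness flows through a single seed fanned out by stable hashing
  (`derive_seed`), so every stage is independently reproducible and the
  pipeline is byte-identical under a fixed config.

## Known limitations

* The headline accuracies of the emulating literature are measured on
  private clinical data and are intentionally out of scope; nothing here
  claims clinical validity.
* Epoch-level cross-validation overstates subject-level generalization;
  use `grouping = "subject"` for the honest variant.
* QDA requires more samples per class than features and is only sensible on
  Top-k subsets; tree/SVM/ensemble baselines are not shipped (no library in
  the target environment).
* The deep models are small CPU implementations; they are adequate for
  ≤ 800-feature inputs and the 30-epoch budget, not a general-purpose
  trainer.
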