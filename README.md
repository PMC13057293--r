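# eegscreen

An R toolkit for EEG-based dyslexia screening pipelines: from raw
multichannel recordings (EDF) to cross-validated classifier benchmarks,
with a deterministic synthetic cohort generator standing in for clinical
data.

## The problem

Dyslexia screening studies increasingly record task-evoked EEG from
children and train classifiers to separate dyslexic from typically
developing readers. A common recipe is:

1. record 16 scalp channels (10–20 montage, midline excluded) at 256 Hz;
2. band-pass 0.1–70 Hz, smooth with a 9-sample moving average, and remove
   ocular/EMG artifacts with ICA;
3. cut each recording into non-overlapping 10-s epochs (34 per subject at
   340 s; a 26/25-subject cohort gives 1,734 epochs);
4. decompose every epoch-channel with the Daubechies-4 DWT at level 6 and
   group coefficients into the classical bands (δ, θ, α, β, optionally γ);
5. for each band × channel compute ten statistics — mean, median, variance
   σ² = (1/N)Σ(xᵢ−x̄)², SD, skewness, kurtosis, IQR, mean absolute
   deviation, RMS, Shannon entropy — giving 10 × 16 × 4 = 640 features per
   epoch;
6. rank features with mRMR (greedy maximization of I(x;C) − mean I(x;S))
   and ReliefF (k-nearest hits/misses weighting), cut Top-k subsets;
7. benchmark shallow/deep feed-forward networks (blocks of dense →
   batch-norm → ReLU → dropout 0.5, Nadam, batch 16, lr 1e-3, ≤30 epochs)
   and classical baselines under segment-level stratified 10-fold CV;
8. characterize features by class effect size (Cohen's d) with
   Benjamini–Hochberg FDR control.

`eegscreen` implements every stage as tested, seedable R code. Clinical
EEG datasets in this domain are private, so the package includes a
synthetic task-evoked cohort generator (`cohort_config()`,
`generate_cohort()`) with band-limited oscillations, 1/f noise, blink and
EMG artifacts, and controllable class effects on band power — see the
methods vignette (`vignettes/methods.Rmd`) for what it does and does not
emulate.

## Worked example

```r
library(eegscreen)

# a small synthetic cohort: 6 subjects, 60 s each, elevated theta/delta in
# the dyslexic class
cfg <- cohort_config(n_dyslexic = 3L, n_control = 3L, duration_s = 60,
                     band_effect_d = c(delta = 1, theta = 1.5, alpha = 0,
                                       beta = 0, gamma = 0),
                     seed = 42L)
fm <- cohort_feature_matrix(cfg, mode = "frequency_consistent")
fm
#> <feature_matrix> 36 epochs x 640 features (6 subjects; labels: 0=18, 1=18)

st <- feature_group_stats(fm)
head(st[order(st$p_fdr), c("feature", "cohens_d", "p_raw", "p_fdr")], 5)
#>               feature cohens_d        p_raw        p_fdr
#> 213 theta.F8.variance 2.480013 2.624469e-08 6.580901e-06
#> 214      theta.F8.std 2.457467 2.812109e-08 6.580901e-06
#> 219      theta.F8.rms 2.445708 3.084797e-08 6.580901e-06
#> 218      theta.F8.mad 2.301707 1.044797e-07 1.671675e-05
#> 279      theta.P4.rms 2.127353 6.181092e-07 7.911798e-05
attr(st, "band_counts")
#> alpha  beta delta theta
#>     0     0    79    83

rk <- relieff_weights(fm, k_neighbors = 5L)
top <- select_top_k(rk, 10L)
rep <- run_cv(subset_features(fm, top$indices),
              model_spec("snn", seed = 1L), n_folds = 5L, seed = 1L)
rep
#> <eval_report> snn, 5 folds, 10 features
#>         accuracy precision recall     f1  auc sensitivity specificity
#> average    81.67     85.33  81.67  80.75 0.94          75       88.33
#> maximum   100.00    100.00 100.00 100.00 1.00         100      100.00
```

Reading the output: the injected theta/delta amplitude effects surface as
large positive Cohen's d on theta/delta amplitude-tracking features
(variance, SD, RMS, MAD), 162 of 640 features survive FDR at α = 0.05 —
all in the two bands that actually carry an effect — ReliefF picks theta
features, and a shallow network cross-validates at ~82% average accuracy
on this deliberately small 36-epoch cohort (small n keeps the example
fast; the full-size stated cohort separates far more cleanly, see
`tests/testthat/test-acceptance.R`).

The package also reproduces closed-form metric arithmetic, e.g. the
confusion matrix TP=83, TN=89, FP=0, FN=2:

```r
unlist(compute_metrics(list(TP = 83, TN = 89, FP = 0, FN = 2)))
#>    accuracy   precision      recall          f1         auc sensitivity
#>   0.9885057   0.9887584   0.9885057   0.9885012          NA   0.9764706
#> specificity
#>   1.0000000
```

i.e. 98.9% accuracy, 97.6% sensitivity, 100% specificity.

## End-to-end pipeline

```r
res <- run_pipeline(pipeline_config(
  out_dir = "run1", seed = 1L,
  simulate = cohort_config(seed = 1L),          # or input_dir = "<EDF dir>"
  mapping_mode = "frequency_consistent",
  eval_specs = list(dnn = model_spec("dnn"))))
```

writes `features.csv`, `ranking_{mrmr,relieff}.csv`, `top_*_k.csv`,
`feature_stats.csv`, `evaluation.csv` and a run log, all reproducible
byte-for-byte from the same config and seed. EDF input mode expects a
directory of recordings plus `manifest.csv` (`subject_id,label,file`).

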