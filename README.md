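# edasleep

Sleep staging and obstructive-sleep-apnoea (OSA) screening from a single
electrodermal activity (EDA) channel.

## The problem

Electrodermal activity — the slow electrical signature of eccrine sweat
glands, which are innervated exclusively by the sympathetic nervous
system — changes with sleep stage and with sleep-disordered breathing.
Phasic EDA *events* (band-limited 0.25–3 Hz oscillations of the skin
potential, classified monophasic/biphasic/triphasic by lobe count) cluster
into *storms* (≥ 1 minute containing ≥ 2 events), and storm load rises with
apnoea severity. If one peripheral channel carried enough of this structure,
much of sleep diagnostics could move from full polysomnography to a
wearable.

`edasleep` implements that question as a tested pipeline, for sleep
researchers and biomedical-signal people:

1. **Synthetic cohorts** (`generate_hypnogram()`, `generate_recording()`,
   `generate_cohort()`): full-night 200 Hz EDA with a cyclic Markov
   hypnogram, stage-dependent planted events, AHI-coupled storm bursts,
   movement artifacts, and complete ground truth — so every downstream
   stage is testable without clinical data.
2. **Signal conditioning** (`preprocess_recording()`): anti-aliased
   downsampling 200 → 35 Hz, whole-night quadratic detrending, 7th-order
   Savitzky–Golay smoothing, 4-level Daubechies-4 wavelet soft-threshold
   denoising, their difference (diffEDA), and order-50 FIR differentiation
   (passband 10 Hz, stopband 12.5 Hz, 50-sample transient discard).
3. **Event/storm detection** (`detect_events()`, `detect_storms()`):
   zero-phase band-pass, lobe segmentation, phase-count classification;
   sliding-window storm rule.
4. **77 per-epoch features** (`extract_features()`): time-domain statistics,
   derivative statistics, periodogram features (including Fisher's g),
   wavelet detail-level statistics, Lyapunov/envelope features, diffEDA
   correlation features, event/storm coverage and energy, and sex.
5. **Correlation-based reduction** (`greedy_reduce()`): the ascending-anchor
   greedy scan at `r_th = 0.8`.
6. **Classification** (`loso_evaluate()`, `personalized_evaluate()`):
   SMOTE-balanced XGBoost for 5/4-stage sleep staging and 3/2-class OSA
   severity, under leave-one-subject-out validation, optionally
   personalized with a seeded 25% of the test subject's night.
7. **Metrics and interpretation** (`macro_scores()`, `adjusted_accuracy()`,
   `shap_report()`): macro F1/recall, accuracy, the mild/severe-collapsing
   adjusted accuracy, row-normalized confusion matrices, and exact
   tree-SHAP feature rankings.

Everything is tibble-first and pipe-friendly; fitted evaluations support
`tidy()`, `glance()`, and `autoplot()`.

## Worked example

Simulate a small cohort with a strong stage signal, extract the feature
matrix, and evaluate four-stage staging under leave-one-subject-out
validation:

```r
library(edasleep)

cohort   <- generate_cohort(4, cohort_scenario("strong", n_epochs = 40), seed = 7)
features <- cohort_features(cohort)
dim(features)
#> [1] 160  82

eval4 <- loso_evaluate(features, "stage4", seed = 7)
eval4
#> <eda_eval> task stage4, loso validation: 4 subjects, 160 epochs
#>   macro F1 0.299 | macro recall 0.312 | accuracy 0.419

tidy(eval4)
#> # A tibble: 4 × 5
#>   subject_id n_epochs macro_f1 macro_recall accuracy
#>   <chr>         <int>    <dbl>        <dbl>    <dbl>
#> 1 S01              40    0.410        0.427    0.475
#> 2 S02              40    0.167        0.139    0.275
#> 3 S03              40    0.458        0.445    0.6
#> 4 S04              40    0.162        0.240    0.325
```

The 82 columns are 5 identifiers (`subject_id`, `epoch`, `stage`, `ahi`,
`odi`) plus the 77 features of `eda_feature_names()`. Chance macro F1 for
four classes is 0.25: even this 4-subject, 20-minute-night toy cohort sits
above it, and the per-fold table shows the subject-to-subject spread that
motivates personalized validation (`personalized_evaluate()` adds a seeded
25% of the held-out night to training). Larger cohorts (10 subjects,
80-epoch nights) reach macro F1 ≈ 0.5 under LOSO; a no-signal cohort stays
at chance — the two-sided sanity harness in the test suite.

`autoplot(eval4)` draws the row-normalized confusion matrix;
`shap_report(model, features)` ranks features by mean |SHAP|.

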