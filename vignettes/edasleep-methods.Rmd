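---
title: "Sleep staging and OSA screening from electrodermal activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging and OSA screening from electrodermal activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electrodermal activity (EDA) reflects eccrine sweat-gland activity driven
exclusively by the sympathetic nervous system. During sleep, phasic EDA
"events" — band-limited (0.25–3 Hz) oscillations of the skin potential —
cluster into "storms", and both their rate and their clustering differ
between sleep stages and with sleep-disordered breathing. This package
implements a complete pipeline that asks how much a *single* EDA channel can
say about (a) the sleep stage of each 30 s epoch and (b) a subject's
obstructive sleep apnoea (OSA) severity, as summarized by the
apnoea–hypopnoea index (AHI) or the oxygen-desaturation index (ODI).

Because full-night polysomnography recordings with an EDA channel are not
freely available, the package ships a calibrated synthetic generator. The
generator is not a fixture: it is first-class, tested code that defines the
study conditions under which every downstream stage is validated.

## The synthetic generator

`generate_hypnogram()` draws a per-epoch stage sequence (W, N1, N2, N3,
REM; 30 s epochs) from a first-order Markov chain with persistence 0.88
(mean bout length ≈ 8 epochs) whose innovation distribution is modulated
along a sleep cycle — deep sleep favoured early in each cycle, REM late,
with ±70% modulation. A fixed-point correction rescales the phase
distributions so that the cycle-averaged innovation distribution equals the
requested stage mix exactly; consequently the long-run stage occupancy
converges to the target mix. The default mix (12.2% W, 16.5% N1, 32.5% N2,
18.2% N3, 20.6% REM) is the stage distribution typical of adult clinical
cohorts.

`generate_recording()` synthesizes the raw 200 Hz trace as a sum of:

* a tonic baseline with a second-order polynomial drift over the night and
  a heavily smoothed random walk (individual sweating patterns differ
  mostly in this tonic behaviour);
* planted events: sine-lobed waveforms (one lobe for monophasic, two for
  biphasic, three for triphasic) with a short Tukey taper, amplitudes drawn
  log-uniformly (default 0.15–0.5 units on a tonic level of ~1) and
  optionally rescaled per stage (`stage_amp_scale`), at the current
  stage's event rate;
* storm bursts: windows of 60–150 s whose nightly count is
  `storm_base + storm_slope * min(AHI, 30)` per hour — the monotone
  coupling between apnoea severity and nocturnal storm load that the OSA
  part of the pipeline is meant to recover;
* rectangular movement artifacts (0.5–2 s, ≥5× the tonic level);
* white measurement noise.

Two generator choices deserve comment.

**Carrier floors.** Event carriers are drawn uniformly from [1.2, 3] Hz for
monophasic and [0.7, 3] Hz for bi-/triphasic events rather than from the
full 0.25–3 Hz detection band. A single-lobe waveform with carrier `f` lasts
`1/(2f)` seconds and necessarily carries low-frequency content; once
band-passed to 0.25–3 Hz, a lobe slower than ~1 Hz acquires compensating
undershoot lobes of 25–50% of its peak, which are indistinguishable from
genuine extra phases. Below these floors a "monophasic event" is simply not
representable inside the band that defines events, so the generator does
not plant such ill-posed shapes.

**Compressed sleep cycles.** `cohort_scenario()` sets the cycle length to a
third of the night, so even short test nights (the default is 120 epochs,
i.e. one hour) contain ~3 full cycles and every subject's night samples all
stages. Synthetic nights are statistical miniatures: what matters to the
pipeline is the per-epoch feature/label joint distribution, not the clock
length of the recording.

**Scenario design.** Three preset scenarios fix the study conditions. The
`"strong"` scenario carries a clear stage signal on two axes: event *rates*
per minute of 3.0 (W), 0.2 (N1), 0.5 (N2), 7.0 (N3) and 1.3 (REM) — wake
rich in small arousal responses, light sleep quiet, deep sleep dominated by
storm-like phasic trains — and event *amplitudes* scaled by 0.5 in wake
and 1.8 in N3. Both axes are needed: on a single count axis, four merged
classes always leave one adjacent pair overlapping at 30 s resolution. The
staging scenarios use a non-OSA cohort without artifacts, because storms
and movement artifacts are stage-independent and only dilute the stage
contrast they are meant to probe. The `"null"` scenario gives every stage
the same rate (1.2/min) — no stage signal by construction — and `"osa"`
restores the full apnoea-severity spread (strata below 5, 5–15, and above
15 events/hour) with movement artifacts, for severity classification and
storm-load analyses.

What the generator deliberately does **not** model: EEG/EOG/EMG or
oxygen-saturation channels, real skin physiology (sweat-duct filling,
electrode polarization), non-stationary noise, or inter-stage transition
dynamics beyond first order. Passing tests on synthetic cohorts therefore
demonstrates that the pipeline recovers the statistical structure it is
pointed at — not that real EDA carries that structure.

## Preprocessing

All conditioning happens at 35 Hz after anti-aliased rational downsampling
by 7/40 (`downsample_eda()`). The resampler is polyphase with a
Kaiser-windowed sinc kernel (10 zero-crossing lobes, β = 10); each
polyphase branch is normalized to unit sum so constants pass through
exactly, and odd-reflection padding removes edge transients. In-band
content (a 1 Hz sine) is reproduced to better than 1e-3; content above the
new Nyquist (17.5 Hz) is attenuated below 1% RMS.

The derived traces are:

* `det_eda` — the raw trace minus its whole-night least-squares quadratic
  (`detrend_poly2()`); the fit spans the entire recording because the trend
  being removed is the subject-specific tonic drift;
* `sg_eda` — a seventh-order Savitzky–Golay filter (`sg_smooth()`), window
  127 samples (~3.6 s). The window length is a package choice: it must
  exceed the order and should suppress content above the 3 Hz event band
  without flattening events; 127 samples puts the first spectral zero near
  3 Hz at 35 Hz sampling;
* `dwt_eda` — four-level periodized Daubechies-4 wavelet decomposition with
  soft thresholding of the detail coefficients (`dwt_denoise()`). The
  threshold is universal, `sigma * sqrt(2 log n)` per level, with `sigma`
  estimated from the median absolute deviation of the level-1 details —
  the standard wavelet-shrinkage default. Daubechies-4 is the conventional
  compact-support choice for EDA; the family is configurable. The
  *thresholded* detail coefficients are kept: the time-frequency features
  summarize them per epoch;
* `diff_eda` — `dwt_eda - sg_eda`, the difference between the two denoised
  versions; it isolates what wavelet shrinkage retains but polynomial
  smoothing removes;
* four derivative traces — first and second FIR derivatives of the raw and
  detrended traces (`fir_derivative()`): a least-squares linear-phase
  differentiator of order 50 with a 10 Hz passband and 12.5 Hz stopband,
  applied once or twice, discarding 50 samples after each pass to remove
  the transient (group delay 25 samples per pass is recorded alongside).
  Against analytic derivatives of an in-band sine the amplitude error is
  0.2% (first) and 0.4% (second derivative). The second derivative is two
  passes of the same filter rather than a dedicated second-difference
  design, so its passband error is the square of the first-order one.
  Derivatives are computed for the raw and detrended traces only — the
  four derivative signals the feature set consumes.

All five equal-length traces are linear, deterministic operators, which the
property tests exploit (`f(a x + b y) = a f(x) + b f(y)`).

## Events and storms

`detect_events()` band-passes the trace (0.25–3 Hz, second-order
Butterworth, zero-phase via forward–backward filtering, odd-reflection
padding) and segments it into zero-crossing-delimited lobes. Working from
the strongest candidate lobe downward, an event is the maximal run of
consecutive lobes whose peaks reach 25% of the event's peak, capped at 12 s;
the lobe count classifies the event (1 → mono±, 2 → bi, ≥3 → tri). A 3 s
refractory zone around each accepted event absorbs residual filter ringing.
The amplitude threshold (default 0.05 units) and the 25% lobe rule are
package parameters: the event definition fixes the band and the phase
taxonomy but not these constants.

`detect_storms()` implements the sliding-window reading of the storm
definition (≥1 min containing ≥2 events): every 60 s window holding two or
more event onsets qualifies, and overlapping qualifying windows merge. Two
events 30 s apart therefore form one 60 s storm; events 120 s apart form
none. Spans are clipped to the recording and never shorter than 60 s.

`event_storm_features()` reduces both interval sets to four per-epoch
numbers: the fraction of epoch samples inside an event (storm) and the
Euclidean norm of the *raw* trace over those samples. Raw rather than
band-passed energy is a documented, configurable convention.

## The 77-variable feature set

Per 30 s epoch (1050 samples at 35 Hz), in a fixed, schema-tested order:
9 time-domain statistics for the raw and detrended traces (mode, median,
max |·|, line length, 10th/75th quantiles, SVD entropy, Teager–Kaiser
energy, Shannon entropy); mean/variance/median/count-above-zero for each of
the four derivative traces; periodogram maximum, its frequency, and
Fisher's g for raw and detrended; six statistics of each wavelet detail
level 1–4; Lyapunov exponent and envelope extrema for raw and detrended;
the diffEDA autocorrelation sum and self-convolution maximum; the four
event/storm features; and sex. Total 18+16+6+24+6+2+4+1 = 77.

Conventions the feature names leave open, fixed here:

* *Mode and Shannon entropy* of a real-valued trace use a shared
  Freedman–Diaconis histogram; a single-bin (constant) epoch has mode =
  median and entropy 0.
* *SVD entropy*: delay-1, dimension-10 embedding; Shannon entropy of the
  normalized singular values; 0 for a constant epoch.
* *Non-linear energy*: the Teager–Kaiser operator averaged over the epoch.
* *Fisher's g*: maximum periodogram ordinate over the ordinate sum, DC
  excluded; an epoch without oscillatory energy returns 0.
* *Lyapunov exponent*: Rosenstein-style largest-exponent estimate
  (dimension 6, delay 1 on a stride-3 thinned epoch, Theiler window 12,
  eight divergence steps, least-squares slope). It is a *complexity index*,
  not a certified dynamical invariant: on a 30 s epoch the estimator is
  validated directionally (≤0 for a sine, >0 for the logistic map at
  r = 4).
* *Envelopes* interpolate local extrema linearly (endpoints included);
  a constant epoch is its own envelope.
* *diffEDA pairings*: the feature names specify "sum of cross-correlation"
  and "maximum convolution value" without naming a second signal; the
  trace is paired with itself. The autocorrelation sum obeys
  `sum(d)^2`, which the tests use as an algebraic oracle.
* *Variance* is the unbiased sample variance throughout.

`fit_feature_normalizer()` standardizes each numeric column to zero mean
and unit variance *on the training subjects only*, and the frozen transform
is applied to test epochs — stricter than normalizing the pooled cohort,
which would leak test-subject statistics into training. Zero-variance
columns are left unscaled with a warning; sex is exempt.

## Correlation-based reduction

`greedy_reduce()` scans the Pearson correlation matrix with anchors in
ascending column order, skipping eliminated anchors, and drops every later
column whose correlation with the anchor exceeds `r_th = 0.8`. Two readings
of the rule are supported: the default thresholds `|r|` (anticorrelated
duplicates are equally redundant); `absolute = FALSE` restores the literal
signed rule. Reduction is fitted inside each validation fold by default
(`reduce_scope = "fold"`); `"global"` reproduces the laxer
fit-once-on-everything protocol. The categorical sex column never enters
the correlation matrix, so it cannot be eliminated. Correctness is pinned
by an independently coded brute-force scan on random correlation
structures, and lowering `r_th` never increases the retained count.

## Classification and validation

Labels: the five scored stages; the four-stage merge (N1+N2 → light,
N3 → deep); and OSA severity from AHI or ODI with the clinical boundaries
<5 (non-OSA), 5 ≤ index < 15 (mild), ≥15 (moderate–severe) — boundary
values land in the higher class. Every epoch inherits its subject's
severity class.

Training folds are rebalanced with SMOTE: each minority class is filled up
to the majority count with convex combinations of a class member and one of
its 5 nearest same-class neighbours; sex and metadata are copied from the
seed sample (the nominal-feature variant). SMOTE runs strictly after the
train/test split and never touches test epochs.

The classifier is an XGBoost tree ensemble (300 rounds, depth 6, learning
rate 0.1, softprob/logistic objective, single-threaded and seeded so runs
reproduce exactly). The hyperparameters are package defaults exposed in
`boost_params()`; no search is performed.

Two protocols:

* **LOSO** (`loso_evaluate()`): each subject in turn is the test set;
  normalization, reduction, SMOTE and fitting happen inside the fold's
  training portion.
* **Personalized** (`personalized_evaluate()`): additionally, a seeded
  random 25% of the left-out subject's epochs joins the training set before
  SMOTE; the other 75% is tested. Per-subject selections derive from one
  master seed. OSA tasks refuse this protocol: severity labels are
  subject-level constants, so personalization would hand the classifier the
  answer.

All randomness (cohort, SMOTE, model, personalization) flows from one
master seed through named substreams.

## Metrics and interpretation

`macro_scores()` computes per-class recall, precision and F1 with the
0/0 → 0 convention and macro-averages over the *full* class vocabulary;
a fold that lacks a class contributes 0 for it, which deliberately
depresses scores under imbalance. `glance()` fold-averages by default
(`aggregate = "pooled"` scores all epochs jointly). `adjusted_accuracy()`
collapses both OSA severities into one class before scoring, so
mild-versus-severe confusions stop counting as errors; it can never be
smaller than the three-class accuracy. `normalized_confusion()` returns
row-stochastic confusion matrices, flagging zero-support rows.

`shap_report()` uses exact tree-SHAP contributions; feature importance is
the mean absolute contribution per feature, summed over class outputs for
multiclass models. Additivity (contributions + bias = margin) is verified
internally to 1e-3 on every call.

## Problem sizes and numerical choices

The test-suite and acceptance-script study conditions are: nights of
60–120 epochs; cohorts of 8–10 subjects for the null/power harnesses and
20 subjects (30-minute nights) for the storm–AHI monotonicity check; these
sizes were chosen as the smallest at which the stochastic checks have
comfortable power. Key numerical conventions: the resampler and
differentiator tolerances quoted above; wavelet reconstruction is exact to
1e-10 when thresholding is disabled; degenerate inputs (constant epochs,
all-zero spectra, single-member classes) follow the explicit conventions
listed per feature rather than producing NaN.

## Known limitations

A consequence of subject-level OSA labels is worth spelling out: in
leave-one-subject-out validation every epoch of the held-out subject shares
one severity class, so the effective sample size of the OSA task is the
number of *subjects*, not of epochs. On desk-scale synthetic cohorts
(~12 subjects) the three-class severity model therefore hovers near
chance even though the storm–AHI coupling itself is clearly recoverable
(the detected storm coverage correlates positively with AHI across
subjects). Meaningful severity classification needs cohorts closer to the
clinical scale of dozens of subjects.

* The generator's realism is statistical, not physiological; absolute
  metric levels on synthetic cohorts do not transfer to clinical data.
  Directional contrasts (null ≈ chance, strong > chance, personalized ≥
  LOSO, storm load increasing with AHI) are the meaningful outputs.
* The Lyapunov and SVD-entropy features are complexity indices whose
  absolute values depend on the documented embedding choices.
* Monophasic events slower than ~1 Hz are outside what the event
  definition can express (see the carrier-floor discussion); real nights
  may contain such activity, which this pipeline would count as bi-/
  triphasic or miss.
* EDF support covers the standard one-channel 16-bit layout the pipeline
  itself writes; EDF+ annexes (annotations, discontinuous records) are out
  of scope.
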