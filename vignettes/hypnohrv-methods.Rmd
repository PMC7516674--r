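---
title: "Hypnopompic HRV analysis: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypnopompic HRV analysis: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiovascular events cluster toward the end of nocturnal sleep and the
minutes after awakening, a window in which sympathetic tone surges. Heart
rate variability (HRV) in the final hour of sleep — the *hypnopompic*
window — is therefore a natural, non-invasive candidate marker of
cardiovascular risk. `hypnohrv` implements the full analysis chain for this
idea: from raw single-channel ECG to a quality-controlled RR-interval
series, to time-domain, frequency-domain and entropy-based HRV metrics, to
an imbalance-aware, cross-validated gradient-boosted-tree classifier that
predicts a two-group cardiovascular outcome from 11 clinical covariates
plus 10 HRV metrics. Because the polysomnography databases this kind of
study draws on are access-restricted, the package also contains a
first-class synthetic-data module that generates ECG traces, RR series and
two-group cohorts with the statistical structure the analysis assumes, so
every stage is testable end to end.

## Signal processing

**R-peak detection.** `detect_r_peaks()` is a faithful Pan-Tompkins chain:
5–15 Hz zero-phase Butterworth band-pass, five-point derivative, squaring,
150 ms moving-window integration, adaptive dual thresholds with search-back
(triggered when no beat is accepted for 1.66 times the running average RR),
a 200 ms refractory period, and refinement of each accepted peak to the
local maximum of the band-passed signal. Thresholds are initialised from
the first two seconds of the integrated signal. These are the canonical
published constants; none of them is tuned.

**Filtering.** `bandpass_filter()` applies a Butterworth band-pass
forward and backward so R-peak timing is not shifted. The signal is
odd-reflection padded before the forward–backward pass; without padding
the slow (0.5 Hz) edge of the band leaves visible transients at the ends of
short records.

**Artifact handling.** Clinical HRV studies typically report that ectopic
beats were corrected by interpolation and recordings with more than 20%
artifacts excluded, without specifying the detection rule. We use
local-median flagging: a beat is flagged when its RR interval deviates from the median
of an 11-beat centred window by more than 20%. This is the standard ectopic
screen and is consistent in vocabulary with the 20% exclusion bound, which
`qc_exclude()` applies strictly (exactly 20% flagged is kept). Flagged
beats are replaced by a natural cubic spline through the unflagged
neighbours (`correct_artifacts()`); unflagged beats are never modified, and
a flagged run covering more than half the series triggers a warning rather
than silent correction.

**Windowing.** `extract_hypnopompic_window()` selects beats whose
cumulative time falls in the half-open interval `[wake − 3600 s, wake)`.
The half-open convention makes beat membership unambiguous; awakening time
is an input, not inferred.

## HRV metrics

**Time domain** (whole hour): SDNN (sample SD, n−1 denominator, stated
explicitly because conventions differ) and RMSSD.

**Frequency domain** (per 5-minute segment, averaged over the 12 segments
of the hour): the tachogram is cubic-spline resampled to 4 Hz, linearly
detrended, and its PSD estimated by a Hann-windowed Welch periodogram with
2-minute sub-windows at 50% overlap — standard Task-Force-era practice for
5-minute spectra. Band powers are trapezoidal integrals over total
(0.003–0.4 Hz), LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) bands; the bin at
the 0.15 Hz boundary belongs to HF (a deterministic tie rule), and
HFnorm = HF/(LF+HF)×100. Because absolute band powers depend on the PSD estimator, they are
comparable only directionally across implementations; the
package's own tests validate the estimator by Parseval (a sinusoid of
amplitude A must yield A²/2 of band power, recovered within 10%).

**Multiscale sample entropy.** `mse_profile()` computes SampEn(m = 2,
r = 0.15 × SD) on coarse-grained copies of the series at scales 1–10. Two
numerical choices matter. First, r is computed **once** from the original
series and reused at every scale — no per-scale renormalisation — so the
profile mixes matching-probability changes with the variance shrinkage of
coarse-graining; that is the intended definition here. Second, zero-match
situations return a flagged `NA`, never infinity; subjects with undefined
metrics are dropped from modelling with a reported count. Matching uses
Chebyshev distance with an inclusive tolerance and excludes self-matches.
The compiled kernel is verified against an independent brute-force pair
counter for exact equality on random series.

**Tied-rank (modified) permutation entropy.** RR intervals measured from a
125 Hz ECG are multiples of 8 ms, so value ties are frequent, and the
original permutation entropy's tie-breaking by order of appearance biases
the pattern distribution. `modified_permutation_entropy()` assigns equal
values equal rank symbols; for m = 4 there are 75 tied-rank patterns (the
ordered set partitions of four items) instead of 24 strict orderings. The
logarithm base is 2 and the embedding delay 1. Base 2 is not arbitrary:
population medians reported for sleeping adults (≈5.6) exceed ln(75) ≈ 4.3 but fit below
log₂(75) ≈ 6.23, so base 2 is the only base consistent with the magnitudes
— and those magnitudes also imply the ties are real, which is why the
synthetic cohort quantises RR values to the 8 ms grid.

## Cohort statistics

Group comparisons follow the usual clinical-reporting logic, implemented as
a pure function of variable type and normality: categorical variables get a
chi-square test; continuous variables are gated through the Lilliefors test
(α = 0.05) in each group and compared by t-test when both pass, Mann-Whitney
otherwise; summaries print mean ± SD or median [Q1, Q3] accordingly. The
Lilliefors p-value comes from the `nortest` implementation.

Under-sampling validation uses the two-sample K-S test plus the
Jensen-Shannon divergence. JSD is computed on shared histogram bins over
the pooled range with Freedman–Diaconis width (minimum 10 bins),
machine-epsilon smoothing of empty cells, and base-2 logarithms so the
value lives in [0, 1]. These binning and base choices are deterministic and scale-adaptive, which is what a
similarity *screen* needs.

## Prediction pipeline

The feature vector has 21 entries: age, gender, BMI, height, waist/hip
ratio, smoking status, lifetime cigarette smoke, diabetes, hypertension,
AHI and RDI, plus TP, LF, HF, HFnorm, SDNN, RMSSD, MSE1, MSE2, MSE10 and
MPE. Categorical covariates are encoded through a declared dictionary;
subjects with missing features are excluded (with a reported count), not
imputed — matching the exclusion-based handling of the study design.

For the short-horizon outcome the control group is under-sampled to the
case count; the draw is re-attempted (deterministic seed offsets, up to
100 tries) until every continuous feature passes the K-S screen at
p > 0.05 against the full control group, and the similarity report is
returned with the experiment. Cross-validation uses stratified folds
whose sizes differ by at most one. Stratification is a design choice: with
70 + 70 subjects, unstratified folds can produce degenerate test-fold
class counts, and the balanced 14/14 folds are consistent with per-fold
percentages that are all multiples of 100/14.

The learner is XGBoost with declared hyperparameters — logistic objective,
maximum depth 3, learning rate 0.1, 100 rounds — chosen as explicit,
logged defaults in place of an unknown, and pluggable through
`boost_hyperparams()`. Classification uses the fixed 0.5 probability
threshold. Performance comes from the confusion matrix with the case group
positive: ACC, TPR, TNR, PPV, F1 (percent) and MCC. Zero-denominator cells
degrade to 0 with a flag so fold averages stay defined. Feature importance
is the split count per feature across the ensemble, normalised to sum to
one. All randomness — under-sampling, folds, learner — derives from one
experiment seed expanded deterministically into stage seeds.

## The synthetic-data generator

`generate_rr_series()` models the pre-awakening tachogram as
`mean_rr + lf_amp·sin(2π·0.1t) + hf_amp·sin(2π·0.25t + φ)` plus broadband
noise with a 1/f^β spectrum (β = 0 white, β = 1 pink), drawn beat by beat
so the next beat occurs one interval later. Optional components: sparse
"erratic beat" excursions (isolated large deviations of the kind seen in
pathological rhythms) and amplitude quantisation to the ECG sampling tick.
`generate_synthetic_ecg()` places Gaussian-shaped QRS deflections at given
beat times — the simplest waveform that exercises a QRS detector — and
`inject_artifacts()` implements the premature-beat motif (one shortened
interval followed by a compensatory lengthening) with a ground-truth mask.

The two-group cohort generator draws the 11 clinical covariates from
normal/log-normal/Bernoulli/multinomial distributions whose control-group
defaults match the medians and quartiles typical of a middle-aged
community sleep cohort, with case-group shifts in the directions epidemiology reports
for incident cardiovascular disease (older, more male, higher BMI,
waist/hip ratio, AHI, RDI, more diabetes and hypertension). Only summary
shapes are matched — the true subject-level distributions of such cohorts
are not public, so the generator reproduces summaries, not the real joint
distribution.

The HRV contrast between groups is produced by three knobs chosen once:
the case group has a steeper noise spectrum (β = 1.0 versus 0.3), slightly
lower oscillation amplitudes and noise SD, and the erratic-beat component
(rate 0.05, 170 ms). This combination is what makes the expected
complexity directions hold *simultaneously*: the steeper spectrum
concentrates variance at low frequency, which (with the tolerance fixed
from the full-series SD) lowers small-scale sample entropy while leaving
more structure to survive coarse-graining (higher MSE10), and the erratic
beats plus quantisation raise ordinal-pattern diversity (higher MPE). A
single spectral knob cannot do this — it moves all scales together.
Between-subject heterogeneity (log-normal spreads of amplitudes and noise,
normal jitter of mean RR and β) gives the wide interquartile ranges real
cohorts show; without it the groups are almost separable and classifier
accuracy saturates at 100%, which no real cohort produces.

What the generator does **not** emulate: realistic multi-lead ECG
morphology, sleep staging or apnea events, circadian drift within the
hour, the correlation structure *between* clinical covariates and HRV
(covariates and RR parameters are drawn independently within group), and
the slightly lower SDNN of case groups (the erratic-beat component
inflates case variance instead). Consequently, passing tests demonstrate
that the pipeline recovers the kinds of structure it is designed for — not
that it would achieve any particular accuracy on clinical data.

## Problem sizes and determinism

The validation suite runs at sizes chosen to make Monte-Carlo conclusions
stable while staying desk-scale: entropy oracle equivalence on 100 random
series up to N = 500; multiscale-profile shape on 100 white + 100 pink
one-hour series; null calibration of the classifier on 200 label
permutations of a 70 + 70 cohort; the acceptance script regenerates a
70-case / 998-control cohort with a full hour of RR per subject. Every
generator and every experiment is deterministic given its seed; identical
seeds give bit-identical outputs, and all stage seeds derive from one
top-level seed.

## Known limitations

* Absolute spectral powers depend on the PSD estimator; only directional
  comparisons with other implementations are meaningful.
* The artifact-detection rule is a documented choice among several common
  ectopic screens, not a canonical standard.
* `HFnorm` of a constant (zero-variance) series is reported as 0/0 → 0 by
  convention, and band powers of near-constant series are numerical noise
  near zero.
* The boosted-tree hyperparameters are declared defaults, not a tuned
  optimum; the package's claims are about the pipeline, not about the best
  achievable accuracy.
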