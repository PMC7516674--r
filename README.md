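# hypnohrv

Heart rate variability (HRV) analysis of the final hour of nocturnal sleep
— the *hypnopompic* window — and prediction of cardiovascular-disease (CVD)
outcomes from the resulting metrics.

Cardiovascular events cluster around the end of sleep and early waking,
when sympathetic activity surges. `hypnohrv` implements the full analysis
chain for studying whether pre-awakening HRV carries predictive
information:

1. **ECG preprocessing** — zero-phase Butterworth band-pass (0.5–45 Hz),
   Pan-Tompkins R-peak detection (derivative → squaring → moving-window
   integration → adaptive dual thresholds with search-back), RR-interval
   computation, local-median artifact flagging, cubic-spline correction,
   and the >20%-artifact exclusion rule.
2. **HRV metrics** — SDNN and RMSSD on the whole hour; Welch-periodogram
   band powers TP (0.003–0.4 Hz), LF (0.04–0.15 Hz), HF (0.15–0.4 Hz) and
   HFnorm = HF/(LF+HF)×100 averaged over twelve 5-minute segments;
   multiscale sample entropy MSE1…MSE10 with SampEn(m = 2, r = 0.15·SD,
   Chebyshev distance, self-matches excluded, r fixed from the original
   series at every scale); and tied-rank (modified) permutation entropy
   (m = 4, base-2), in which equal values share a rank symbol — for m = 4
   there are 75 such patterns, so MPE ∈ [0, log₂75].
3. **Cohort statistics** — chi-square / t / Mann-Whitney comparisons gated
   by the Lilliefors normality test, two-sample Kolmogorov-Smirnov, and a
   bounded base-2 Jensen-Shannon divergence for distribution similarity.
4. **Prediction** — a 21-entry feature vector (11 clinical covariates +
   10 HRV metrics), class-imbalance handling by similarity-validated
   under-sampling, stratified 5-fold cross-validated XGBoost, the six
   confusion-matrix measures ACC, TPR, TNR, PPV, F1 and MCC, split-count
   feature importance, and a clinical-only ablation with relative-change
   reporting.
5. **Synthetic data** — generators for QRS-bearing ECG, RR series with
   controllable LF/HF oscillations, 1/f^β broadband noise, erratic beats,
   artifacts and 8 ms quantisation, and two-group cohorts with realistic
   covariate distributions, so the entire pipeline is testable without
   access to clinical recordings.

## Worked example

```r
library(hypnohrv)

## 1. From ECG to a clean RR series
rr_true <- generate_rr_series(rr_gen_params(duration = 600, quantize_ms = 8, seed = 7))
ecg <- generate_synthetic_ecg(cumsum(rr_true$rr) / 1000, fs = 125,
                              noise_sd = 0.1, seed = 8)
rr <- compute_rr(detect_r_peaks(ecg$ecg))
rr <- flag_artifacts(rr)
qc_exclude(rr)$exclude
#> [1] FALSE
rr <- correct_artifacts(rr)
rr
#> <rr_series> 601 beats, 599.4 s, mean RR 997.4 ms, 0 flagged (0.0%), origin: corrected

## 2. HRV metrics
round(sdnn(rr), 1); round(rmssd(rr), 1)
#> [1] 49.2
#> [1] 40
average_band_powers(lapply(segment_rr(rr, 300), band_powers))
#> <spectral_bands> TP 1671.0  LF 821.9  HF 552.2 ms^2, HFnorm 40.2 n.u.
mse_profile(rr)
#> <entropy_profile> m = 2, r = 7.381 ms, MPE(m = 4) = 5.465 bits
#>  MSE1  MSE2  MSE3  MSE4  MSE5  MSE6  MSE7  MSE8  MSE9 MSE10
#> 2.779 2.365 2.498 2.024 2.015 2.331 2.110 1.238 1.281 1.121

## 3. A small two-group experiment
cohort <- generate_cohort(cohort_effect_config(n_control = 30, n_case = 30, seed = 42))
features <- compute_hrv_features(cohort)
compare_groups(cbind(cohort$subjects, MSE1 = features$MSE1), "MSE1")
#> MSE1: 2.3[2.2,2.5] vs 2.0[1.8,2.1]; mann-whitney test, p = 4.215e-07
run_experiment(cohort$subjects, features, mode = "short",
               feature_set = "full", seed = 42)
#> <hrv_experiment> full features, n = 60, 5-fold CV (seed 42)
#> average: ACC 73.3%  TPR 73.3%  TNR 73.3%  PPV 73.9%  F1 73.2%  MCC 0.47
#> top features by split count:
#>     feature splits   relative
#> 1      MSE1     61 0.23106061
#> 2     MSE10     47 0.17803030
#> 3       MPE     32 0.12121212
#> 4 waist_hip     31 0.11742424
#> 5       bmi     20 0.07575758
```

The RR series comes back from detection with every beat intact (the QC
fraction is 0%, so the recording is kept), the band powers and entropy
profile summarise the hour's autonomic structure, the case group's lower
scale-1 entropy is picked up as a highly significant Mann-Whitney
difference, and the cross-validated classifier recovers the injected group
signal with the entropy metrics ranking at the top of the split-count
importance table.

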