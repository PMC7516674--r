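test_that("band-pass filter removes DC and keeps in-band components", {
  fs <- 125
  t <- seq(0, 20, by = 1 / fs)
  dc <- ecg_signal(rep(0.7, length(t)), fs)
  out <- bandpass_filter(dc, 0.5, 45)
  expect_lt(max(abs(out$samples)), 0.05)
  expect_length(out$samples, length(t))

  inband <- ecg_signal(sin(2 * pi * 10 * t), fs)
  g10 <- bandpass_filter(inband, 0.5, 45)
  mid <- seq(2 * fs, length(t) - 2 * fs)  # avoid filter edge transients
  amp10 <- max(abs(g10$samples[mid]))
  expect_equal(amp10, 1, tolerance = 0.05)

  mains <- ecg_signal(sin(2 * pi * 60 * t), fs)
  g60 <- bandpass_filter(mains, 0.5, 45)
  expect_lt(max(abs(g60$samples[mid])), 0.1)  # > 90% attenuation out of band

  expect_error(bandpass_filter(dc, 0.5, 70), "fs/2")
})

test_that("Pan-Tompkins finds every beat of a clean synthetic ECG", {
  g <- generate_synthetic_ecg(seq(1, 60), fs = 125, noise_sd = 0)
  det <- detect_r_peaks(g$ecg)
  st <- peak_match_stats(det$peaks, g$peaks, tol = 2)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$precision, 1)
  expect_true(all(diff(det$peaks) > 0))
})

test_that("Pan-Tompkins stays above 99% sensitivity and precision under noise", {
  rr <- generate_rr_series(rr_gen_params(duration = 300, seed = 21))
  g <- generate_synthetic_ecg(cumsum(rr$rr) / 1000, fs = 125,
                              noise_sd = 0.1, seed = 22)  # 10% of QRS amplitude
  det <- detect_r_peaks(g$ecg)
  st <- peak_match_stats(det$peaks, g$peaks, tol = 3)
  expect_gte(st$sensitivity, 0.99)
  expect_gte(st$precision, 0.99)
})

test_that("a flat signal yields zero peaks with a warning", {
  flat <- ecg_signal(rep(1, 125 * 30), fs = 125)
  expect_warning(det <- detect_r_peaks(flat), "flat")
  expect_length(det$peaks, 0)
})

test_that("RR computation from peaks is exact interval arithmetic", {
  expect_equal(compute_rr(rpeak_series(c(1, 126, 251), 125))$rr, c(1000, 1000))
  expect_equal(compute_rr(rpeak_series(c(1, 101, 226), 125))$rr, c(800, 1000))
  pk <- rpeak_series(cumsum(c(1, rep(100, 9))), 125)
  expect_length(compute_rr(pk)$rr, 9)
  expect_error(compute_rr(rpeak_series(5L, 125)), "two peaks")
})

test_that("detection plus RR computation reproduces the generated tachogram", {
  rr_true <- generate_rr_series(rr_gen_params(duration = 180, noise_sd = 30,
                                              quantize_ms = 8, seed = 31))
  g <- generate_synthetic_ecg(cumsum(rr_true$rr) / 1000, fs = 125, noise_sd = 0)
  rr_det <- compute_rr(detect_r_peaks(g$ecg))
  expect_length(rr_det$rr, length(rr_true$rr) - 1)
  # each interval within 2 samples (16 ms at 125 Hz) of quantisation error
  expect_lt(max(abs(rr_det$rr - rr_true$rr[-1])), 16.0001)
})

test_that("local-median artifact flagging finds deviant beats and only those", {
  clean <- rr_series(rep(1000, 50))
  expect_false(any(flag_artifacts(clean)$mask))

  one_bad <- rr_series(c(rep(1000, 20), 500, rep(1000, 20)))
  fl <- flag_artifacts(one_bad, rel_threshold = 0.2)
  expect_true(fl$mask[21])
  expect_equal(sum(fl$mask), 1)
})

test_that("the flagger recovers at least 90% of injected artifacts", {
  rr <- generate_rr_series(rr_gen_params(duration = 600, seed = 41))
  inj <- inject_artifacts(rr, 0.10, seed = 42)
  fl <- flag_artifacts(inj$rr)
  recall <- sum(fl$mask & inj$truth) / sum(inj$truth)
  expect_gte(recall, 0.90)
})

test_that("spline correction is exact on polynomial trends and improves noisy fits", {
  ramp <- rr_series(800 + 2 * (1:40), mask = c(rep(FALSE, 19), TRUE, rep(FALSE, 20)))
  fixed <- correct_artifacts(ramp)
  expect_equal(fixed$rr[20], 800 + 2 * 20, tolerance = 1e-8)
  expect_equal(fixed$rr[-20], ramp$rr[-20])  # unflagged beats untouched
  expect_equal(fixed$origin, "corrected")

  ident <- correct_artifacts(rr_series(c(900, 910, 905)))
  expect_equal(ident$rr, c(900, 910, 905))

  t <- seq(0, 500, by = 0.9)
  true <- 900 + 80 * sin(2 * pi * t / 60)
  inj <- inject_artifacts(rr_series(true), 0.05, seed = 43)
  corrected <- correct_artifacts(flag_artifacts(inj$rr))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(corrected$rr, true), rmse(inj$rr$rr, true))
})

test_that("QC exclusion applies a strict greater-than bound and is monotone", {
  mk <- function(nbad) rr_series(rep(1000, 100), mask = seq_len(100) <= nbad)
  expect_false(qc_exclude(mk(10))$exclude)
  expect_false(qc_exclude(mk(20))$exclude)   # exactly 20% is kept
  expect_true(qc_exclude(mk(21))$exclude)
  fractions <- vapply(0:100, function(k) qc_exclude(mk(k))$exclude, logical(1))
  expect_true(all(diff(fractions) >= 0))     # monotone in flagged fraction
})

test_that("hypnopompic window extraction selects the final hour of beats", {
  rr <- rr_series(rep(1000, 7200))  # 2 h of 1000 ms beats
  win <- extract_hypnopompic_window(rr, wake_time = 7200)
  expect_equal(length(win$rr), 3600)
  expect_error(extract_hypnopompic_window(rr, wake_time = 8000), "ends before")
  expect_error(extract_hypnopompic_window(rr, wake_time = 3000, window = 3600),
               "before the recording")
})
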