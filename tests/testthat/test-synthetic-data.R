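test_that("RR generator with no variability sources yields a constant series", {
  rr <- generate_rr_series(rr_gen_params(mean_rr = 800, lf_amp = 0, hf_amp = 0,
                                         noise_sd = 0, duration = 120, seed = 1))
  expect_true(all(rr$rr == 800))
  expect_false(any(rr$mask))
  expect_equal(rr$origin, "synthetic")
  expect_equal(length(rr$rr), ceiling(120 / 0.8), tolerance = 0.02)
})

test_that("RR generator is deterministic, positive, and of the right duration", {
  p <- rr_gen_params(duration = 300, seed = 99)
  a <- generate_rr_series(p)
  b <- generate_rr_series(p)
  expect_identical(a$rr, b$rr)
  expect_true(all(a$rr > 0))
  expect_gte(rr_duration(a), 300)
  expect_lt(rr_duration(a), 300 + max(a$rr) / 1000 + 1)
  c2 <- generate_rr_series(rr_gen_params(duration = 300, seed = 100))
  expect_false(identical(a$rr, c2$rr))
})

test_that("RR generator rejects invalid parameters", {
  expect_error(rr_gen_params(mean_rr = -5), "mean_rr")
  expect_error(rr_gen_params(duration = 0), "duration")
  expect_error(rr_gen_params(noise_sd = -1), "noise_sd")
  expect_error(rr_gen_params(spike_rate = 1.5), "spike_rate")
})

test_that("pure-LF tachogram has essentially no HF-band power downstream", {
  rr <- generate_rr_series(rr_gen_params(lf_amp = 40, hf_amp = 0, noise_sd = 0,
                                         duration = 300, seed = 3))
  b <- band_powers(rr)
  expect_lt(b["HFnorm"], 5)
  expect_gt(b["LF"], 100)
})

test_that("synthetic ECG places detectable peaks at the requested beats", {
  g <- generate_synthetic_ecg(seq(1, 10), fs = 125, noise_sd = 0)
  det <- detect_r_peaks(g$ecg)
  expect_length(det$peaks, 10)
  expect_true(all(abs(det$peaks - g$peaks) <= 2))
})

test_that("synthetic ECG handles the empty beat list and is deterministic", {
  g0 <- generate_synthetic_ecg(numeric(0), fs = 125, noise_sd = 0, duration = 12)
  expect_true(all(g0$ecg$samples == 0))
  expect_length(g0$peaks, 0)
  g1 <- generate_synthetic_ecg(1:5, fs = 125, noise_sd = 0.05, seed = 7)
  g2 <- generate_synthetic_ecg(1:5, fs = 125, noise_sd = 0.05, seed = 7)
  expect_identical(g1$ecg$samples, g2$ecg$samples)
  expect_error(generate_synthetic_ecg(c(2, 1, 3), fs = 125), "increasing")
})

test_that("artifact injection perturbs exactly the requested beat count", {
  rr <- generate_rr_series(rr_gen_params(duration = 120, seed = 5))
  id <- inject_artifacts(rr, 0, seed = 1)
  expect_identical(id$rr$rr, rr$rr)
  expect_false(any(id$truth))

  rr100 <- rr_series(rep(1000, 100), origin = "synthetic")
  inj <- inject_artifacts(rr100, 0.25, seed = 2)
  expect_equal(sum(inj$truth), 25)
  expect_error(inject_artifacts(rr100, 1.2), "fraction")
})

test_that("a 25% artifact load pushes the QC decision over the exclusion bound", {
  rr <- generate_rr_series(rr_gen_params(duration = 600, seed = 8))
  inj <- inject_artifacts(rr, 0.25, seed = 3)
  flagged <- flag_artifacts(inj$rr)
  expect_true(qc_exclude(flagged, 0.20)$exclude)
})

test_that("cohort generation is deterministic and has the configured size", {
  cfg <- cohort_effect_config(n_control = 12, n_case = 8, rr_duration = 60, seed = 4)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(nrow(a$subjects), 20)
  expect_equal(sum(a$subjects$group == "CVD"), 8)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$rr[[5]]$rr, b$rr[[5]]$rr)
  expect_length(a$rr, 20)
})

test_that("null cohorts produce nominal K-S rejection rates on continuous covariates", {
  # age is rounded to whole years, which makes its K-S conservative; use the
  # genuinely continuous covariates for the size check
  vars <- c("bmi", "height", "waist_hip", "ahi", "rdi")
  pvals <- unlist(lapply(1:25, function(s) {
    coh <- generate_cohort(null_cohort_config(n_control = 60, n_case = 60,
                                              rr_duration = 30, seed = 1000 + s))
    vapply(vars, function(v) {
      ks_two_sample(coh$subjects[[v]][coh$subjects$group == "nonCVD"],
                    coh$subjects[[v]][coh$subjects$group == "CVD"])$p.value
    }, numeric(1))
  }))
  # 125 null tests: rejection rate should sit near the nominal 5% level
  expect_gte(mean(pvals < 0.05), 0.005)
  expect_lte(mean(pvals < 0.05), 0.12)
})

test_that("default case-group effects order the complexity medians as configured", {
  fix <- effect_cohort_fixture()
  med <- function(v) tapply(fix$features[[v]], fix$subjects$group, median)
  # cases: less small-scale entropy, more large-scale entropy, more
  # ordinal-pattern diversity, less spectral power
  expect_lt(med("MSE1")[["CVD"]], med("MSE1")[["nonCVD"]])
  expect_lt(med("MSE2")[["CVD"]], med("MSE2")[["nonCVD"]])
  expect_gt(med("MSE10")[["CVD"]], med("MSE10")[["nonCVD"]])
  expect_gt(med("MPE")[["CVD"]], med("MPE")[["nonCVD"]])
  expect_lt(med("LF")[["CVD"]], med("LF")[["nonCVD"]])
  expect_lt(med("HF")[["CVD"]], med("HF")[["nonCVD"]])
})

test_that("cohort subject-table round-trips through delimited text", {
  coh <- generate_cohort(cohort_effect_config(n_control = 5, n_case = 3,
                                              rr_duration = 30, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$group, coh$subjects$group)
  expect_equal(back$bmi, coh$subjects$bmi, tolerance = 1e-6)
})

test_that("RR series round-trip through delimited text with mask and origin", {
  rr <- rr_series(c(810, 1200, 805), mask = c(FALSE, TRUE, FALSE), origin = "corrected")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rr(rr, path)
  back <- read_rr(path)
  expect_equal(back$rr, rr$rr)
  expect_equal(back$mask, rr$mask)
  expect_equal(back$origin, "corrected")
})
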