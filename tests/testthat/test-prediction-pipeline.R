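mk_subjects <- function(n) {
  generate_cohort(null_cohort_config(n_control = n / 2, n_case = n / 2,
                                     rr_duration = 30, seed = 81))$subjects
}

test_that("feature assembly yields 21 features, or 11 clinical-only", {
  subj <- mk_subjects(20)
  hrv <- as.data.frame(matrix(rnorm(20 * 16), 20,
                              dimnames = list(NULL, c("TP", "LF", "HF", "HFnorm",
                                                      "SDNN", "RMSSD", paste0("MSE", 1:9), "MPE"))))
  hrv$MSE10 <- rnorm(20)
  full <- assemble_features(subj, hrv, "full")
  expect_equal(ncol(full$x), 21)
  expect_equal(nrow(full$x), 20)
  clin <- assemble_features(subj, feature_set = "clinical_only")
  expect_equal(ncol(clin$x), 11)

  hrv2 <- hrv; hrv2$MPE[3] <- NA
  expect_message(dropped <- assemble_features(subj, hrv2, "full"), "dropped")
  expect_equal(nrow(dropped$x), 19)
  expect_equal(dropped$n_dropped, 1)

  subj_bad <- subj
  levels(subj_bad$smoking) <- c(levels(subj_bad$smoking), "pipe")
  subj_bad$smoking[1] <- "pipe"
  expect_error(assemble_features(subj_bad, hrv, "full"), "unknown category")
})

test_that("confusion-matrix metrics reproduce worked examples exactly", {
  m <- metrics_from_confusion(confusion_matrix(tp = 11, fn = 3, fp = 2, tn = 12))
  expect_equal(unname(m["ACC"]), 82.1, tolerance = 0.05)
  expect_equal(unname(m["TPR"]), 78.6, tolerance = 0.05)
  expect_equal(unname(m["TNR"]), 85.7, tolerance = 0.05)
  expect_equal(unname(m["PPV"]), 84.6, tolerance = 0.05)
  expect_equal(unname(m["F1"]), 81.5, tolerance = 0.05)
  expect_equal(round(unname(m["MCC"]), 2), 0.64)

  perfect <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_equal(unname(perfect[c("ACC", "TPR", "TNR", "PPV", "F1")]),
               rep(100, 5))
  expect_equal(unname(perfect["MCC"]), 1)

  expect_error(metrics_from_confusion(confusion_matrix(0, 0, 0, 0)), "empty")
  expect_error(confusion_matrix(-1, 0, 0, 5), "non-negative")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(82)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(1:30, 1))
    m <- metrics_from_confusion(cm)
    tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      expect_equal(unname(m["F1"]), 100 * 2 * tp / (2 * tp + fp + fn), tolerance = 1e-9)
    }
    expect_gte(m["MCC"], -1); expect_lte(m["MCC"], 1)
    # ACC is the prevalence-weighted combination of TPR and TNR
    prev <- (tp + fn) / (tp + fn + fp + tn)
    expect_equal(unname(m["ACC"]),
                 unname(prev * m["TPR"] + (1 - prev) * m["TNR"]), tolerance = 1e-9)
  }
})

test_that("zero-denominator metrics degrade to zero instead of NaN", {
  m <- metrics_from_confusion(confusion_matrix(0, 0, 0, 8))
  expect_equal(unname(m["TPR"]), 0)
  expect_equal(unname(m["PPV"]), 0)
  expect_equal(unname(m["MCC"]), 0)
  expect_true(attr(m, "degenerate"))
})

test_that("the CV report averages fold metrics field-wise", {
  cms <- list(confusion_matrix(11, 3, 2, 12), confusion_matrix(9, 5, 2, 12),
              confusion_matrix(14, 0, 4, 10), confusion_matrix(11, 3, 1, 13),
              confusion_matrix(12, 2, 4, 10))
  rep5 <- cv_report(cms)
  expect_equal(unname(rep5$average["ACC"]), mean(rep5$folds[, "ACC"]))
  expect_equal(dim(rep5$folds), c(5, 6))
  same <- cv_report(list(confusion_matrix(8, 2, 3, 7), confusion_matrix(8, 2, 3, 7)))
  expect_equal(unname(same$average), unname(same$folds[1, ]))
  expect_error(cv_report(list(confusion_matrix(1, 1, 1, 1))), "two folds")
})

test_that("relative change follows the growth-over-reference convention", {
  expect_equal(round(relative_change(81.4, 73.5), 1), 10.7)
  expect_equal(round(relative_change(0.64, 0.46), 1), 39.1)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(1, 0), "non-zero")
})

test_that("stratified folds balance classes and partition the data", {
  y <- rep(c(0, 1), each = 70)
  fold <- kfold_split(y, k = 5, seed = 83)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 28))
  expect_true(all(table(fold, y) == 14))       # 14/14 per fold after stratification
  expect_identical(fold, kfold_split(y, k = 5, seed = 83))
  expect_false(identical(fold, kfold_split(y, k = 5, seed = 84)))
  expect_error(kfold_split(1:3, k = 5), "exceeds")

  y2 <- c(rep(0, 11), rep(1, 7))
  f2 <- kfold_split(y2, k = 4, seed = 85)
  expect_lte(diff(range(table(f2))), 1)        # fold sizes differ by <= 1
})

test_that("the boosted-tree learner fits separable data and rejects one-class input", {
  set.seed(86)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] > 0)
  model <- train_classifier(x, y)
  expect_equal(mean(predict(model, x, type = "class") == y), 1)
  expect_error(train_classifier(x, rep(1L, 100)), "both classes")
})

test_that("split-count importance is normalised and ranks signal over noise", {
  set.seed(87)
  x <- cbind(signal = rnorm(300), noise = rnorm(300))
  y <- as.integer(x[, "signal"] + 0.3 * rnorm(300) > 0)
  model <- train_classifier(x, y)
  imp <- feature_importance(model)
  expect_equal(sum(imp$relative), 1)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$relative[imp$feature == "signal"],
            imp$relative[imp$feature == "noise"])
  expect_error(feature_importance(list()), "fitted")
})

test_that("under-sampling returns a validated, deterministic, representative subset", {
  subj <- generate_cohort(cohort_effect_config(n_control = 500, n_case = 1,
                                               rr_duration = 30, seed = 88))$subjects
  ctrl <- subj[subj$group == "nonCVD", ]
  us <- undersample_controls(ctrl, 70, seed = 89)
  expect_equal(nrow(us$subset), 70)
  expect_true(all(us$report$ks_p > 0.05))
  expect_true(all(us$report$jsd < 0.1))
  us2 <- undersample_controls(ctrl, 70, seed = 89)
  expect_identical(us$indices, us2$indices)

  full <- undersample_controls(ctrl, nrow(ctrl), seed = 90)
  expect_equal(nrow(full$subset), nrow(ctrl))
  expect_true(all(full$report$D == 0))
  expect_error(undersample_controls(ctrl, 1000, seed = 1), "exceeds")
})

test_that("experiments are bit-reproducible under a fixed seed", {
  fix <- effect_cohort_fixture()
  e1 <- run_experiment(fix$subjects, fix$features, mode = "short",
                       feature_set = "full", seed = 91)
  e2 <- run_experiment(fix$subjects, fix$features, mode = "short",
                       feature_set = "full", seed = 91)
  expect_identical(e1$cv$folds, e2$cv$folds)
  expect_identical(e1$importance, e2$importance)
  expect_equal(e1$n, 140)  # 70 cases + 70 under-sampled controls
})

test_that("clinical-only ablation uses 11 features and reports relative changes", {
  fix <- effect_cohort_fixture()
  ab <- run_ablation(fix$subjects, fix$features, mode = "short", seed = 92)
  expect_equal(ncol(ab$full$importance) , 3)
  expect_equal(nrow(ab$clinical_only$importance), 11)
  expect_equal(nrow(ab$full$importance), 21)
  expect_equal(unname(ab$relative_change["ACC"]),
               relative_change(ab$clinical_only$cv$average[["ACC"]],
                               ab$full$cv$average[["ACC"]]))
})
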