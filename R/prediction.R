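#' Binary confusion matrix
#'
#' Counts of a two-class prediction outcome, with the case (CVD) group as
#' the positive class.
#'
#' @param tp,fn,fp,tn Non-negative counts: true positives, false negatives,
#'   false positives, true negatives.
#' @return An object of class `confusion_matrix`.
#' @examples
#' metrics_from_confusion(confusion_matrix(11, 3, 2, 12))
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d  FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Performance metrics from a confusion matrix
#'
#' The six standard binary-classification measures: accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, sensitivity/recall `TPR = TP/(TP+FN)`,
#' specificity `TNR = TN/(TN+FP)`, precision `PPV = TP/(TP+FP)`,
#' `F1 = 2 PPV TPR / (PPV + TPR)` and the Matthews correlation coefficient
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' ACC, TPR, TNR, PPV and F1 are reported in percent, MCC on its natural
#' `[-1, 1]` scale. Any zero denominator yields 0 for that measure (with a
#' `degenerate` attribute set), so fold averages stay defined.
#'
#' @param cm A [confusion_matrix] with a positive total count.
#' @return An object of class `performance_metrics`: named numeric vector
#'   `ACC`, `TPR`, `TNR`, `PPV`, `F1` (percent) and `MCC`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * ppv * tpr, ppv + tpr)
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)
  degenerate <- (tp + fn == 0) || (tn + fp == 0) || (tp + fp == 0) || mcc_den == 0
  structure(c(ACC = 100 * acc, TPR = 100 * tpr, TNR = 100 * tnr,
              PPV = 100 * ppv, F1 = 100 * f1, MCC = mcc),
            class = "performance_metrics", degenerate = degenerate)
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  TPR %.1f%%  TNR %.1f%%  PPV %.1f%%  F1 %.1f%%  MCC %.2f\n",
              x["ACC"], x["TPR"], x["TNR"], x["PPV"], x["F1"], x["MCC"]))
  invisible(x)
}

#' Cross-validation report from per-fold confusion matrices
#'
#' @param cms List of >= 2 [confusion_matrix] objects, one per test fold.
#' @param seed Optional seed annotation.
#' @return An object of class `cv_report`: list with `folds` (matrix of
#'   per-fold metrics), `average` (field-wise arithmetic mean), `k`, `seed`.
#' @export
cv_report <- function(cms, seed = NA_integer_) {
  if (length(cms) < 2L) stop("at least two folds required")
  folds <- do.call(rbind, lapply(cms, function(cm) unclass(metrics_from_confusion(cm))))
  rownames(folds) <- paste0("fold", seq_len(nrow(folds)))
  structure(list(folds = folds,
                 average = structure(colMeans(folds), class = "performance_metrics"),
                 k = length(cms), confusion = cms, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation\n", x$k))
  print(round(x$folds, 2))
  cat("average: ")
  print(x$average)
  invisible(x)
}

#' Relative change between two metric values
#'
#' `(new - reference) / reference x 100`, e.g. the relative improvement of
#' one model's average accuracy over another's.
#'
#' @param new_value,reference_value Numeric scalars; `reference_value != 0`.
#' @return Percent change.
#' @examples
#' relative_change(81.4, 73.5)  # +10.7
#' @export
relative_change <- function(new_value, reference_value) {
  if (reference_value == 0) stop("reference value must be non-zero")
  (new_value - reference_value) / reference_value * 100
}

#' Stratified k-fold split
#'
#' Partitions samples into k folds whose sizes differ by at most one,
#' stratified by class label so every fold keeps the overall class balance
#' as closely as possible.
#'
#' @param y Class labels (vector, length n >= k).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
kfold_split <- function(y, k = 5L, seed = 1L) {
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > n) stop("'k' exceeds the number of samples")
  restore <- set_local_seed(seed)
  on.exit(restore())
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Default boosted-tree hyperparameters
#'
#' The declared learner configuration: logistic objective, maximum tree
#' depth 3, learning rate 0.1, 100 boosting rounds. All experiment runs log
#' these values.
#'
#' @param max_depth,eta,nrounds Usual gradient-boosting knobs.
#' @return Named list.
#' @export
boost_hyperparams <- function(max_depth = 3L, eta = 0.1, nrounds = 100L) {
  list(max_depth = max_depth, eta = eta, nrounds = nrounds,
       objective = "binary:logistic")
}

#' Train the gradient-boosted-tree classifier
#'
#' Fits an XGBoost binary classifier with the declared hyperparameters. The
#' returned object wraps the booster together with the feature names so
#' split-count importance can be extracted later.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y 0/1 labels; both classes must be present.
#' @param hyper Hyperparameter list from [boost_hyperparams()].
#' @param seed Integer seed for the learner.
#' @return An object of class `hrv_classifier`.
#' @export
train_classifier <- function(x, y, hyper = boost_hyperparams(), seed = 1L) {
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  restore <- set_local_seed(seed)
  on.exit(restore())
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = hyper$objective, max_depth = hyper$max_depth,
                  eta = hyper$eta, nthread = 1),
    data = dtrain, nrounds = hyper$nrounds, verbose = 0
  )
  structure(list(booster = booster, feature_names = colnames(x), hyper = hyper),
            class = "hrv_classifier")
}

#' Predict case probability / class with a fitted classifier
#'
#' @param object An `hrv_classifier`.
#' @param newdata Feature matrix.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   0.5 threshold.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.hrv_classifier <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$booster, as.matrix(newdata))
  if (type == "class") as.integer(p > 0.5) else p
}

#' Split-count feature importance
#'
#' A feature's importance is the number of times it is used to split a node
#' across all trees of the ensemble; relative importance divides by the
#' total split count so the column sums to 1. Sorted descending.
#'
#' @param model A fitted `hrv_classifier`.
#' @return An object of class `importance_table`: data.frame with `feature`,
#'   `splits`, `relative`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "hrv_classifier")) stop("'model' must be a fitted hrv_classifier")
  trees <- xgboost::xgb.model.dt.tree(model = model$booster)
  used <- trees$Feature[trees$Feature != "Leaf"]
  counts <- table(factor(used, levels = model$feature_names))
  out <- data.frame(feature = names(counts), splits = as.integer(counts),
                    stringsAsFactors = FALSE)
  total <- sum(out$splits)
  out$relative <- if (total > 0) out$splits / total else 0
  out <- out[order(-out$splits), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' Under-sample the control group with distribution-similarity validation
#'
#' Draws a uniform random subset of `target_n` control subjects and checks,
#' feature by feature, that the subset still represents the full control
#' group: two-sample K-S test p > 0.05 on every continuous feature. Up to
#' `max_tries` draws (each with a deterministic seed offset) are attempted;
#' if none passes, the draw with the largest minimum K-S p-value is returned
#' with a warning. The returned report also carries the Jensen-Shannon
#' divergence per feature.
#'
#' @param table Data.frame of control-group subjects.
#' @param target_n Subset size (<= `nrow(table)`).
#' @param seed Integer seed.
#' @param variables Continuous feature names to validate; defaults to all
#'   numeric columns except `id`.
#' @param max_tries Maximum number of re-draws (default 100).
#' @return List with `subset` (data.frame), `indices`, `report` (from
#'   [similarity_report()]) and `tries`.
#' @export
undersample_controls <- function(table, target_n, seed = 1L,
                                 variables = NULL, max_tries = 100L) {
  n <- nrow(table)
  if (target_n > n) stop("'target_n' exceeds the control group size")
  variables <- variables %||% setdiff(
    names(table)[vapply(table, is.numeric, logical(1))], "id")
  best <- NULL; best_minp <- -Inf
  for (try in seq_len(max_tries)) {
    restore <- set_local_seed(seed + (try - 1L) * 10007L)
    idx <- sort(sample.int(n, target_n))
    restore()
    rep_ <- similarity_report(table[idx, , drop = FALSE], table, variables)
    minp <- min(rep_$ks_p)
    if (minp > best_minp) {
      best <- list(subset = table[idx, , drop = FALSE], indices = idx,
                   report = rep_, tries = try)
      best_minp <- minp
    }
    if (minp > 0.05) return(best)
  }
  warning("no subset passed the K-S similarity screen in ", max_tries,
          " draws; returning the best draw (min p = ", signif(best_minp, 3), ")")
  best
}

# deterministic stage seeds derived from one experiment seed (double
# arithmetic to avoid 32-bit overflow before the modulus)
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               (.Machine$integer.max - 1))
}

#' Run a cross-validated prediction experiment
#'
#' End-to-end orchestration of one risk-prediction run on an assembled
#' feature set: stratified k-fold split, per-fold boosted-tree training and
#' evaluation at the 0.5 probability threshold, metric aggregation, and
#' split-count feature importance from a final model fitted on all data.
#' All randomness (fold split, learner) derives deterministically from
#' `seed`.
#'
#' @param features An `hrv_features` object from [assemble_features()].
#' @param k Number of CV folds (default 5).
#' @param hyper Learner hyperparameters ([boost_hyperparams()]).
#' @param seed Integer seed.
#' @return An object of class `hrv_experiment`: list with `cv` (a
#'   [cv_report]), `importance` (an importance table), `feature_set`, `k`,
#'   `hyper`, `seed`, `n`.
#' @export
run_cv_experiment <- function(features, k = 5L, hyper = boost_hyperparams(),
                              seed = 1L) {
  stopifnot(inherits(features, "hrv_features"))
  x <- features$x; y <- features$y
  fold <- kfold_split(y, k = k, seed = stage_seed(seed, 1L))
  cms <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    model <- train_classifier(x[tr, , drop = FALSE], y[tr], hyper,
                              seed = stage_seed(seed, 10L + f))
    pred <- predict(model, x[te, , drop = FALSE], type = "class")
    confusion_matrix(tp = sum(pred == 1 & y[te] == 1),
                     fn = sum(pred == 0 & y[te] == 1),
                     fp = sum(pred == 1 & y[te] == 0),
                     tn = sum(pred == 0 & y[te] == 0))
  })
  full_model <- train_classifier(x, y, hyper, seed = stage_seed(seed, 99L))
  structure(list(cv = cv_report(cms, seed = seed),
                 importance = feature_importance(full_model),
                 feature_set = features$feature_set, k = k,
                 hyper = hyper, seed = seed, n = length(y)),
            class = "hrv_experiment")
}

#' @export
print.hrv_experiment <- function(x, ...) {
  cat(sprintf("<hrv_experiment> %s features, n = %d, %d-fold CV (seed %d)\n",
              x$feature_set, x$n, x$k, x$seed))
  cat("average: ")
  print(x$cv$average)
  cat("top features by split count:\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' Run a full prediction experiment on a cohort
#'
#' Orchestrates the study design for one outcome horizon: in `"short"` mode
#' the control (nonCVD) group is under-sampled to the case count with
#' distribution-similarity validation before cross-validation, emulating
#' imbalance-aware short-horizon prediction; in `"long"` mode all subjects
#' enter the CV directly. Features are assembled per `feature_set`.
#'
#' @param subjects Cohort subject table (with `group` column).
#' @param hrv HRV feature block row-parallel to `subjects` (from
#'   [compute_hrv_features()]); may be `NULL` for clinical-only runs.
#' @param mode `"short"` (balanced by under-sampling) or `"long"` (all
#'   subjects).
#' @param feature_set `"full"` or `"clinical_only"`.
#' @param k CV folds (default 5).
#' @param hyper Learner hyperparameters.
#' @param seed Integer seed governing under-sampling, folds and learner.
#' @return An `hrv_experiment`; in short mode it additionally carries
#'   `similarity` (the under-sampling [similarity_report()]).
#' @export
run_experiment <- function(subjects, hrv = NULL,
                           mode = c("short", "long"),
                           feature_set = c("full", "clinical_only"),
                           k = 5L, hyper = boost_hyperparams(), seed = 1L) {
  mode <- match.arg(mode)
  feature_set <- match.arg(feature_set)
  similarity <- NULL
  if (mode == "short") {
    is_ctrl <- subjects$group == "nonCVD"
    n_case <- sum(!is_ctrl)
    ctrl_idx <- which(is_ctrl)
    us <- undersample_controls(subjects[ctrl_idx, , drop = FALSE], n_case,
                               seed = stage_seed(seed, 500L))
    keep <- sort(c(which(!is_ctrl), ctrl_idx[us$indices]))
    similarity <- us$report
    subjects <- subjects[keep, , drop = FALSE]
    if (!is.null(hrv)) hrv <- hrv[keep, , drop = FALSE]
  }
  feats <- assemble_features(subjects, hrv, feature_set)
  out <- run_cv_experiment(feats, k = k, hyper = hyper, seed = seed)
  out$mode <- mode
  out$similarity <- similarity
  out
}

#' Ablation: full feature set versus clinical covariates only
#'
#' Runs the same experiment twice — once with the 21-feature set, once with
#' the 11 clinical covariates only — under identical seeds, and reports the
#' relative change of each averaged metric when the HRV block is removed.
#'
#' @inheritParams run_experiment
#' @return List with `full`, `clinical_only` (both `hrv_experiment`) and
#'   `relative_change` (percent change of each averaged metric,
#'   clinical-only relative to full).
#' @export
run_ablation <- function(subjects, hrv, mode = c("short", "long"),
                         k = 5L, hyper = boost_hyperparams(), seed = 1L) {
  mode <- match.arg(mode)
  full <- run_experiment(subjects, hrv, mode, "full", k, hyper, seed)
  clin <- run_experiment(subjects, hrv, mode, "clinical_only", k, hyper, seed)
  delta <- mapply(relative_change, unclass(clin$cv$average), unclass(full$cv$average))
  list(full = full, clinical_only = clin, relative_change = delta)
}
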