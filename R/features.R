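#' Compute the per-subject HRV metric block for a cohort
#'
#' For every subject's RR series: SDNN and RMSSD on the whole series,
#' frequency-domain band powers averaged over consecutive 5-minute segments,
#' the multiscale sample entropy profile (scales 1-10, m = 2,
#' r = 0.15 x SD) and the tied-rank permutation entropy (m = 4).
#'
#' @param cohort An `hrv_cohort` from [generate_cohort()], or a list of
#'   [rr_series].
#' @param segment_length Spectral segment duration, s (default 300).
#' @param progress Print a dot every 50 subjects (default FALSE).
#' @return Data.frame with one row per subject: `TP`, `LF`, `HF`, `HFnorm`,
#'   `SDNN`, `RMSSD`, `MSE1`..`MSE10`, `MPE`.
#' @export
compute_hrv_features <- function(cohort, segment_length = 300, progress = FALSE) {
  rr_list <- if (inherits(cohort, "hrv_cohort")) cohort$rr else cohort
  rows <- lapply(seq_along(rr_list), function(i) {
    if (progress && i %% 50 == 0) cat(".")
    rr <- rr_list[[i]]
    bands <- average_band_powers(lapply(segment_rr(rr, segment_length), band_powers))
    ent <- mse_profile(rr)
    c(unclass(bands), SDNN = sdnn(rr), RMSSD = rmssd(rr), ent$mse, MPE = ent$mpe)
  })
  if (progress) cat("\n")
  as.data.frame(do.call(rbind, rows))
}

# Clinical covariates in feature order, with their numeric encodings.
clinical_feature_names <- c("age", "gender", "bmi", "height", "waist_hip",
                            "smoking", "cigs_py", "diabetes", "hypertension",
                            "ahi", "rdi")
hrv_feature_names <- c("TP", "LF", "HF", "HFnorm", "SDNN", "RMSSD",
                       "MSE1", "MSE2", "MSE10", "MPE")

encode_clinical <- function(subjects) {
  enc <- subjects[clinical_feature_names]
  dict <- list(gender = c(F = 0, M = 1),
               smoking = c(never = 0, current = 1, former = 2),
               diabetes = c(no = 0, yes = 1),
               hypertension = c(no = 0, yes = 1))
  for (col in names(dict)) {
    v <- as.character(enc[[col]])
    bad <- !is.na(v) & !v %in% names(dict[[col]])
    if (any(bad)) stop("unknown category label in '", col, "': ", v[which(bad)[1]])
    enc[[col]] <- unname(dict[[col]][v])
  }
  data.matrix(enc)
}

#' Assemble the modelling feature matrix
#'
#' Builds the per-subject feature vector used by the risk models: 11
#' clinical covariates (categoricals encoded through a declared dictionary)
#' plus 10 HRV metrics (TP, LF, HF, HFnorm, SDNN, RMSSD, MSE1, MSE2, MSE10,
#' MPE) — 21 features in the full set, 11 in the clinical-only ablation.
#' Subjects with any missing feature value are dropped and their count
#' reported, mirroring exclusion rather than imputation.
#'
#' @param subjects Data.frame of clinical covariates with a `group` column.
#' @param hrv Data.frame from [compute_hrv_features()], row-parallel to
#'   `subjects`. May be `NULL` for `feature_set = "clinical_only"`.
#' @param feature_set `"full"` (21 features) or `"clinical_only"` (11).
#' @return An object of class `hrv_features`: list with `x` (numeric
#'   matrix), `y` (0/1 outcome, 1 = case/CVD), `group` (factor),
#'   `feature_set` and `n_dropped`.
#' @export
assemble_features <- function(subjects, hrv = NULL,
                              feature_set = c("full", "clinical_only")) {
  feature_set <- match.arg(feature_set)
  x <- encode_clinical(subjects)
  if (feature_set == "full") {
    if (is.null(hrv)) stop("'hrv' block required for the full feature set")
    stopifnot(nrow(hrv) == nrow(subjects))
    x <- cbind(x, data.matrix(hrv[hrv_feature_names]))
  }
  y <- as.integer(subjects$group == "CVD")
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped for missing feature values")
  }
  structure(list(x = x[complete, , drop = FALSE], y = y[complete],
                 group = factor(subjects$group[complete]),
                 feature_set = feature_set, n_dropped = n_dropped),
            class = "hrv_features")
}

#' @export
print.hrv_features <- function(x, ...) {
  cat(sprintf("<hrv_features> %d subjects x %d features (%s), %d dropped\n",
              nrow(x$x), ncol(x$x), x$feature_set, x$n_dropped))
  invisible(x)
}
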