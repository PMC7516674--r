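#' Configuration of a two-group synthetic cohort
#'
#' Describes a control ("nonCVD") group by per-variable distribution
#' parameters and a case ("CVD") group by additive shifts / probability
#' differences on top of them, for the eleven clinical covariates used in
#' cardiovascular risk modelling plus the RR-generator parameters of each
#' group. Continuous covariates are drawn from normal or log-normal
#' distributions whose defaults match the medians and quartiles typical of a
#' middle-aged community sleep cohort; categorical covariates are Bernoulli
#' or multinomial.
#'
#' The default case-group shifts point in the directions observed in
#' incident-CVD cohorts: older, more often male, higher BMI, waist/hip ratio
#' and sleep-disordered-breathing indices, more diabetes and hypertension,
#' slightly lower spectral HRV power, and altered complexity (lower
#' small-scale multiscale entropy, higher large-scale entropy and higher
#' tied-rank permutation entropy, obtained through a steeper noise spectrum
#' plus sparse erratic beats).
#'
#' @param n_control,n_case Group sizes (>= 1).
#' @param baseline Named list of control-group distribution parameters; see
#'   the default for the full set. The `rr` entry holds the group-level
#'   RR-generator parameters and `rr_dispersion` the between-subject spread
#'   around them (log-normal multipliers for amplitudes and noise, normal
#'   jitter for mean RR and the spectral exponent), which produces the wide
#'   interquartile ranges characteristic of population HRV.
#' @param deltas Named list of case-group effects. Continuous variables use
#'   additive shifts (`age`, `height`, `waist_hip`) or log-scale shifts
#'   (`bmi`, `ahi`, `rdi`, `cigs_py`); probabilities use additive differences
#'   (`male_p`, `diabetes_p`, `hypertension_p`, `smoking_p` as a vector over
#'   never/current/former); `rr` is a named list of [rr_gen_params] field
#'   offsets. Set every entry to 0 for a null cohort.
#' @param rr_duration Duration of each subject's RR series, s.
#' @param seed Integer seed.
#' @return An object of class `cohort_effect_config`.
#' @export
cohort_effect_config <- function(n_control = 998L, n_case = 70L,
                                 baseline = NULL, deltas = NULL,
                                 rr_duration = 3600, seed = 1L) {
  if (n_control < 1L || n_case < 1L) stop("group sizes must be >= 1")
  base_default <- list(
    age = list(mean = 61, sd = 12),                 # years
    male_p = 0.392,
    bmi = list(meanlog = log(27.1), sdlog = 0.16),  # kg/m^2
    height = list(mean = 166, sd = 11),             # cm
    waist_hip = list(mean = 89, sd = 10.5),         # ratio x 100
    smoking_p = c(never = 0.546, current = 0.071, former = 0.383),
    cigs_zero_p = 0.55,                             # never-smoker mass at 0
    cigs = list(meanlog = log(20), sdlog = 0.9),    # packs/year when > 0
    diabetes_p = 0.033,
    hypertension_p = 0.336,
    ahi = list(meanlog = log(8.3), sdlog = 1.2),    # events/h
    rdi = list(meanlog = log(26.9), sdlog = 0.63),  # events/h
    rr = list(mean_rr = 1000, lf_amp = 32.5, hf_amp = 24.8,
              noise_sd = 55, noise_beta = 0.3,
              spike_rate = 0, spike_amp = 0, quantize_ms = 8),
    # between-subject heterogeneity of the RR-generator parameters; the
    # log-normal spreads reproduce the wide interquartile ranges of
    # spectral power seen across a community cohort
    rr_dispersion = list(mean_rr_sd = 70, lf_amp_sdlog = 0.37,
                         hf_amp_sdlog = 0.5, noise_sd_sdlog = 0.22,
                         noise_beta_sd = 0.15, spike_rate_sdlog = 0.4)
  )
  delta_default <- list(
    age = 3, male_p = 0.081, bmi = log(28.2 / 27.1), height = 1.7,
    waist_hip = 5.6, smoking_p = c(never = -0.047, current = 0.002, former = 0.045),
    cigs_zero_p = -0.05, cigs = 0.1, diabetes_p = 0.039, hypertension_p = 0.079,
    ahi = log(9.9 / 8.3), rdi = log(30.3 / 26.9),
    rr = list(lf_amp = -1.0, hf_amp = -2.4, noise_sd = -12,
              noise_beta = 0.7, spike_rate = 0.05, spike_amp = 170)
  )
  baseline <- utils::modifyList(base_default, baseline %||% list())
  deltas <- utils::modifyList(delta_default, deltas %||% list())
  for (p in c("male_p", "diabetes_p", "hypertension_p", "cigs_zero_p")) {
    pc <- baseline[[p]]; pv <- pc + (deltas[[p]] %||% 0)
    if (pc < 0 || pc > 1 || pv < 0 || pv > 1) stop("probability out of [0, 1]: ", p)
  }
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 baseline = baseline, deltas = deltas,
                 rr_duration = rr_duration, seed = as.integer(seed)),
            class = "cohort_effect_config")
}

#' A zero-effect (null) cohort configuration
#'
#' Convenience wrapper: both groups are drawn from identical distributions,
#' so any detected group difference is a false positive. Used for type-I
#' error and null-calibration checks.
#'
#' @inheritParams cohort_effect_config
#' @param ... Passed to [cohort_effect_config()].
#' @return A `cohort_effect_config` whose deltas are all zero.
#' @export
null_cohort_config <- function(n_control = 70L, n_case = 70L, ...) {
  cohort_effect_config(
    n_control = n_control, n_case = n_case,
    deltas = list(age = 0, male_p = 0, bmi = 0, height = 0, waist_hip = 0,
                  smoking_p = c(never = 0, current = 0, former = 0),
                  cigs_zero_p = 0, cigs = 0, diabetes_p = 0, hypertension_p = 0,
                  ahi = 0, rdi = 0,
                  rr = list(lf_amp = 0, hf_amp = 0, noise_sd = 0,
                            noise_beta = 0, spike_rate = 0, spike_amp = 0)),
    ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_group <- function(n, b, group_label) {
  smoking_p <- pmin(pmax(b$smoking_p, 0), 1)
  smoking_p <- smoking_p / sum(smoking_p)
  cigs <- ifelse(stats::runif(n) < b$cigs_zero_p, 0,
                 stats::rlnorm(n, b$cigs$meanlog, b$cigs$sdlog))
  data.frame(
    group = factor(rep(group_label, n), levels = c("nonCVD", "CVD")),
    age = round(pmax(stats::rnorm(n, b$age$mean, b$age$sd), 40)),
    gender = factor(ifelse(stats::runif(n) < b$male_p, "M", "F"), levels = c("F", "M")),
    bmi = stats::rlnorm(n, b$bmi$meanlog, b$bmi$sdlog),
    height = stats::rnorm(n, b$height$mean, b$height$sd),
    waist_hip = stats::rnorm(n, b$waist_hip$mean, b$waist_hip$sd),
    smoking = factor(sample(names(smoking_p), n, replace = TRUE, prob = smoking_p),
                     levels = c("never", "current", "former")),
    cigs_py = cigs,
    diabetes = factor(ifelse(stats::runif(n) < b$diabetes_p, "yes", "no"),
                      levels = c("no", "yes")),
    hypertension = factor(ifelse(stats::runif(n) < b$hypertension_p, "yes", "no"),
                          levels = c("no", "yes")),
    ahi = stats::rlnorm(n, b$ahi$meanlog, b$ahi$sdlog),
    rdi = stats::rlnorm(n, b$rdi$meanlog, b$rdi$sdlog)
  )
}

apply_deltas <- function(b, d) {
  b$age$mean <- b$age$mean + (d$age %||% 0)
  b$male_p <- b$male_p + (d$male_p %||% 0)
  b$bmi$meanlog <- b$bmi$meanlog + (d$bmi %||% 0)
  b$height$mean <- b$height$mean + (d$height %||% 0)
  b$waist_hip$mean <- b$waist_hip$mean + (d$waist_hip %||% 0)
  if (!is.null(d$smoking_p)) b$smoking_p <- b$smoking_p + d$smoking_p
  b$cigs_zero_p <- b$cigs_zero_p + (d$cigs_zero_p %||% 0)
  b$cigs$meanlog <- b$cigs$meanlog + (d$cigs %||% 0)
  b$diabetes_p <- b$diabetes_p + (d$diabetes_p %||% 0)
  b$hypertension_p <- b$hypertension_p + (d$hypertension_p %||% 0)
  b$ahi$meanlog <- b$ahi$meanlog + (d$ahi %||% 0)
  b$rdi$meanlog <- b$rdi$meanlog + (d$rdi %||% 0)
  for (nm in names(d$rr %||% list())) {
    b$rr[[nm]] <- (b$rr[[nm]] %||% 0) + d$rr[[nm]]
  }
  b
}

#' Generate a two-group synthetic cohort
#'
#' Draws clinical covariates for a control and a case group from the
#' configured distributions and attaches one synthetic pre-awakening RR
#' series per subject, generated with the group's RR parameters. The whole
#' draw is deterministic given `config$seed`.
#'
#' @param config A [cohort_effect_config].
#' @return An object of class `hrv_cohort`: list with `subjects` (a
#'   data.frame of group label and the 11 clinical covariates, one row per
#'   subject), `rr` (list of [rr_series], parallel to the rows) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_effect_config(n_control = 3, n_case = 2,
#'                                             rr_duration = 120, seed = 7))
#' coh$subjects$group
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_effect_config"))
  restore <- set_local_seed(config$seed)
  on.exit(restore())
  case_base <- apply_deltas(config$baseline, config$deltas)
  subjects <- rbind(
    draw_group(config$n_control, config$baseline, "nonCVD"),
    draw_group(config$n_case, case_base, "CVD")
  )
  subjects <- cbind(id = seq_len(nrow(subjects)), subjects)
  n <- nrow(subjects)
  rr_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rr_par <- list(nonCVD = config$baseline$rr, CVD = case_base$rr)
  disp <- config$baseline$rr_dispersion
  subject_pars <- lapply(seq_len(n), function(i) {
    base <- rr_par[[as.character(subjects$group[i])]]
    list(
      mean_rr = max(500, stats::rnorm(1, base$mean_rr, disp$mean_rr_sd)),
      lf_amp = base$lf_amp * stats::rlnorm(1, 0, disp$lf_amp_sdlog),
      hf_amp = base$hf_amp * stats::rlnorm(1, 0, disp$hf_amp_sdlog),
      noise_sd = base$noise_sd * stats::rlnorm(1, 0, disp$noise_sd_sdlog),
      noise_beta = max(0, stats::rnorm(1, base$noise_beta, disp$noise_beta_sd)),
      spike_rate = min(0.2, base$spike_rate * stats::rlnorm(1, 0, disp$spike_rate_sdlog)),
      spike_amp = base$spike_amp,
      quantize_ms = base$quantize_ms %||% 0
    )
  })
  rr <- lapply(seq_len(n), function(i) {
    generate_rr_series(do.call(rr_gen_params, c(
      subject_pars[[i]], list(duration = config$rr_duration, seed = rr_seeds[i])
    )))
  })
  structure(list(subjects = subjects, rr = rr, config = config),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<hrv_cohort> %d subjects (%s), RR duration %g s\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$config$rr_duration))
  invisible(x)
}

#' Write / read a synthetic cohort table
#'
#' The subject table is written as tab-separated text with a data-dictionary
#' header (one `# column:` line per variable); RR series are not serialised
#' here (see [write_rr()]).
#'
#' @param cohort An `hrv_cohort` or a subject data.frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  subjects <- if (inherits(cohort, "hrv_cohort")) cohort$subjects else cohort
  dict <- c(
    "# column: id = subject identifier",
    "# column: group = outcome group (nonCVD | CVD)",
    "# column: age = age, years",
    "# column: gender = sex (F | M)",
    "# column: bmi = body mass index, kg/m^2",
    "# column: height = height, cm",
    "# column: waist_hip = waist/hip ratio x 100",
    "# column: smoking = smoking status (never | current | former)",
    "# column: cigs_py = lifetime cigarette smoke, packs/year",
    "# column: diabetes = diabetes (no | yes)",
    "# column: hypertension = hypertension (no | yes)",
    "# column: ahi = apnea-hypopnea index, events/h",
    "# column: rdi = respiratory disturbance index, events/h"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(dict, con)
  utils::write.table(subjects, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$group <- factor(tab$group, levels = c("nonCVD", "CVD"))
  for (col in c("gender", "smoking", "diabetes", "hypertension")) {
    if (col %in% names(tab)) tab[[col]] <- factor(tab[[col]])
  }
  tab
}
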