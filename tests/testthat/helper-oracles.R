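# Independent brute-force oracle for sample entropy: direct O(N^2) pair
# counting over all template pairs i < j, vectorised over j per i.
brute_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    js <- (i + 1):nt
    d <- abs(x[i] - x[js])
    for (k in seq_len(m - 1)) d <- pmax(d, abs(x[i + k] - x[js + k]))
    hit <- d <= r
    B <- B + sum(hit)
    if (any(hit)) {
      jh <- js[hit]
      A <- A + sum(abs(x[i + m] - x[jh + m]) <= r)
    }
  }
  c(A = A, B = B)
}

brute_sampen <- function(x, m, r) {
  cnt <- brute_sampen_counts(x, m, r)
  if (cnt["B"] == 0 || cnt["A"] == 0) return(NA_real_)
  unname(-log(cnt["A"] / cnt["B"]))
}

# Match detected against true peak indices within a sample tolerance.
peak_match_stats <- function(detected, truth, tol = 2) {
  sens <- mean(vapply(truth, function(p) any(abs(detected - p) <= tol), logical(1)))
  prec <- if (length(detected)) {
    mean(vapply(detected, function(p) any(abs(truth - p) <= tol), logical(1)))
  } else 0
  list(sensitivity = sens, precision = prec)
}

# Shared effect cohort (default case-group contrasts, 70/70) with its HRV
# feature block; computed lazily once per test run and reused by the cohort
# direction, ablation and null-calibration checks.
.fixture_cache <- new.env(parent = emptyenv())

effect_cohort_fixture <- function() {
  if (is.null(.fixture_cache$effect)) {
    cfg <- cohort_effect_config(n_control = 70, n_case = 70, seed = 20260920)
    coh <- generate_cohort(cfg)
    feat <- compute_hrv_features(coh)
    .fixture_cache$effect <- list(subjects = coh$subjects, features = feat)
  }
  .fixture_cache$effect
}
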