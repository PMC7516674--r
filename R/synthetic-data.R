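#' Parameters for the synthetic RR-interval generator
#'
#' The generator models the pre-awakening tachogram as a mean level plus two
#' sinusoidal modulations in the classical low-frequency (~0.1 Hz, baroreflex
#' / Mayer-wave band) and high-frequency (~0.25 Hz, respiratory sinus
#' arrhythmia band) ranges, plus broadband noise whose power spectrum falls
#' off as 1/f^beta. `noise_beta = 0` gives white beat-to-beat noise,
#' `noise_beta = 1` the 1/f-like structure typical of healthy heart rate.
#' An optional sparse "erratic beat" component adds isolated large
#' beat-to-beat excursions of the kind seen in pathological rhythms.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param lf_amp Amplitude of the low-frequency oscillation, ms.
#' @param hf_amp Amplitude of the high-frequency oscillation, ms.
#' @param noise_sd Standard deviation of the broadband noise, ms.
#' @param noise_beta Spectral exponent of the broadband noise (>= 0).
#' @param lf_freq,hf_freq Oscillation frequencies, Hz.
#' @param spike_rate Expected fraction of beats carrying an erratic
#'   excursion (0 disables).
#' @param spike_amp Amplitude of an erratic excursion, ms.
#' @param quantize_ms Amplitude quantisation step, ms: RR intervals measured
#'   from a digitised ECG are multiples of the sampling period (8 ms at
#'   125 Hz), which produces the heavy value ties that tied-rank permutation
#'   entropy is designed for. 0 (default) disables quantisation.
#' @param duration Total duration to generate, s.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `rr_gen_params`.
#' @export
rr_gen_params <- function(mean_rr = 1000, lf_amp = 30, hf_amp = 25,
                          noise_sd = 40, noise_beta = 1,
                          lf_freq = 0.1, hf_freq = 0.25,
                          spike_rate = 0, spike_amp = 0, quantize_ms = 0,
                          duration = 3600, seed = 1L) {
  if (!is.finite(mean_rr) || mean_rr <= 0) stop("'mean_rr' must be positive")
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_beta < 0) stop("'noise_beta' must be >= 0")
  if (spike_rate < 0 || spike_rate > 1) stop("'spike_rate' must be in [0, 1]")
  if (quantize_ms < 0) stop("'quantize_ms' must be >= 0")
  structure(list(
    mean_rr = mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
    noise_sd = noise_sd, noise_beta = noise_beta,
    lf_freq = lf_freq, hf_freq = hf_freq,
    spike_rate = spike_rate, spike_amp = spike_amp,
    quantize_ms = quantize_ms,
    duration = duration, seed = as.integer(seed)
  ), class = "rr_gen_params")
}

# Zero-mean, unit-SD noise with power spectral density ~ 1/f^beta, generated
# by amplitude-shaping the DFT of white Gaussian noise.
spectral_noise <- function(n, beta) {
  if (n < 2L) return(rep(0, n))
  w <- stats::rnorm(n)
  if (beta == 0) return(as.numeric(scale(w)))
  W <- stats::fft(w)
  k <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))  # two-sided bin index
  gain <- ifelse(k == 0, 0, k^(-beta / 2))
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic RR-interval series
#'
#' Draws the tachogram beat by beat: the instantaneous RR interval at beat
#' time t is `mean_rr + lf_amp sin(2 pi f_LF t) + hf_amp sin(2 pi f_HF t +
#' phi)` plus broadband noise, and the next beat occurs one interval later.
#' Generated intervals are floored at 250 ms so the series stays
#' physiologically positive even under extreme noise settings.
#'
#' @param params An [rr_gen_params] object.
#' @return An [rr_series] with origin `"synthetic"` and an empty artifact
#'   mask, of total duration approximately `params$duration`.
#' @examples
#' rr <- generate_rr_series(rr_gen_params(duration = 300, seed = 42))
#' rr
#' @export
generate_rr_series <- function(params) {
  stopifnot(inherits(params, "rr_gen_params"))
  p <- params
  n_max <- ceiling(p$duration / (p$mean_rr / 1000)) + 64L
  rr <- numeric(n_max)
  restore <- set_local_seed(p$seed)
  on.exit(restore())
  noise <- if (p$noise_sd > 0) p$noise_sd * spectral_noise(n_max, p$noise_beta) else numeric(n_max)
  hf_phase <- stats::runif(1, 0, 2 * pi)
  spikes <- if (p$spike_rate > 0) {
    (stats::runif(n_max) < p$spike_rate) * p$spike_amp *
      sign(stats::runif(n_max) - 0.5)
  } else numeric(n_max)
  t <- 0; i <- 0L
  while (t < p$duration && i < n_max) {
    i <- i + 1L
    val <- p$mean_rr +
      p$lf_amp * sin(2 * pi * p$lf_freq * t) +
      p$hf_amp * sin(2 * pi * p$hf_freq * t + hf_phase) +
      noise[i] + spikes[i]
    val <- max(val, 250)
    if (p$quantize_ms > 0) val <- round(val / p$quantize_ms) * p$quantize_ms
    rr[i] <- val
    t <- t + rr[i] / 1000
  }
  rr_series(rr[seq_len(i)], origin = "synthetic")
}

# Evaluate an expression under a local RNG seed, restoring the caller's RNG
# state afterwards. Returns the restore function for use with on.exit().
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a synthetic single-channel ECG with known R-peak positions
#'
#' Places one Gaussian-shaped QRS-like deflection (amplitude 1 mV, width
#' ~10 ms) at each requested beat time on a flat baseline, adds white
#' measurement noise, and returns the ground-truth peak sample indices. The
#' waveform is deliberately minimal: it exercises a QRS detector without
#' claiming clinical morphology.
#'
#' @param beat_times Strictly increasing beat times, s.
#' @param fs Sampling rate, Hz (default 125).
#' @param noise_sd White noise SD, mV.
#' @param seed Integer seed.
#' @param qrs_width Gaussian sigma of the QRS template, s.
#' @param duration Total trace duration, s; defaults to covering the last
#'   beat plus one second.
#' @return List with `ecg` (an [ecg_signal]) and `peaks` (integer sample
#'   indices of the true R peaks, 1-based).
#' @export
generate_synthetic_ecg <- function(beat_times, fs = 125, noise_sd = 0, seed = 1L,
                                   qrs_width = 0.01, duration = NULL) {
  if (fs <= 0) stop("'fs' must be positive")
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0)) {
    stop("'beat_times' must be strictly increasing")
  }
  if (is.null(duration)) {
    duration <- if (length(beat_times)) max(beat_times) + 1 else 1
  }
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  peaks <- integer(0)
  for (bt in beat_times) {
    # only evaluate the template near the beat
    lo <- max(1L, floor((bt - 6 * qrs_width) * fs))
    hi <- min(n, ceiling((bt + 6 * qrs_width) * fs) + 1L)
    win <- lo:hi
    sig[win] <- sig[win] + exp(-((tt[win] - bt)^2) / (2 * qrs_width^2))
    peaks <- c(peaks, which.min(abs(tt - bt)))
  }
  if (noise_sd > 0) {
    restore <- set_local_seed(seed)
    on.exit(restore())
    sig <- sig + stats::rnorm(n, sd = noise_sd)
  }
  list(ecg = ecg_signal(sig, fs = fs), peaks = peaks)
}

#' Inject ectopic-like artifacts into an RR series
#'
#' Perturbs `round(fraction * N)` beats with a premature-beat pattern: the
#' selected interval is shortened to 55% of its value and the following
#' interval lengthened by the removed time (compensatory pause). The
#' returned truth mask marks the shortened beats. Selected beats are spaced
#' at least two positions apart where feasible so perturbations do not
#' overlap.
#'
#' @param rr An [rr_series].
#' @param fraction Fraction of beats to perturb, in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `rr` (perturbed [rr_series], mask empty) and `truth`
#'   (logical vector marking perturbed beats).
#' @export
inject_artifacts <- function(rr, fraction, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("'fraction' must be in [0, 1]")
  }
  n <- length(rr$rr)
  k <- round(fraction * n)
  truth <- rep(FALSE, n)
  if (k == 0L) {
    return(list(rr = rr_series(rr$rr, origin = rr$origin), truth = truth))
  }
  restore <- set_local_seed(seed)
  on.exit(restore())
  candidates <- sample(seq_len(max(n - 1L, 1L)))
  chosen <- integer(0)
  for (idx in candidates) {
    if (length(chosen) >= k) break
    if (!length(chosen) || min(abs(chosen - idx)) > 2L) chosen <- c(chosen, idx)
  }
  # relax spacing if the requested fraction is too dense for the gap rule
  if (length(chosen) < k) {
    extra <- setdiff(candidates, chosen)
    chosen <- c(chosen, extra[seq_len(k - length(chosen))])
  }
  out <- rr$rr
  for (idx in chosen) {
    removed <- out[idx] * 0.45
    out[idx] <- out[idx] - removed
    if (idx < n) out[idx + 1L] <- out[idx + 1L] + removed
  }
  truth[chosen] <- TRUE
  list(rr = rr_series(out, origin = rr$origin), truth = truth)
}
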