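#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward
#' (`signal::filtfilt`), so the pass band is shaped twice and the phase
#' response is zero — R-peak timing is not shifted.
#'
#' @param ecg An [ecg_signal].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs / 2`.
#' @param order Filter order of the underlying Butterworth design.
#' @return A filtered [ecg_signal] of the same length.
#' @export
bandpass_filter <- function(ecg, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(ecg, "ecg_signal"))
  nyq <- ecg$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- ecg$samples
  n <- length(x)
  # odd-reflection padding keeps the forward-backward pass free of edge
  # transients (the padding must cover the slow edge of the band)
  p <- min(n - 1L, as.integer(ceiling(3 * ecg$fs / low)))
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  out <- signal::filtfilt(bf, xp)[(p + 1L):(p + n)]
  ecg_signal(out, fs = ecg$fs, start_time = ecg$start_time)
}

#' Detect R-wave peaks with the Pan-Tompkins algorithm
#'
#' The classical QRS detection chain: band-pass 5-15 Hz to isolate QRS
#' energy, five-point derivative, squaring, and moving-window integration
#' (150 ms), followed by adaptive dual-threshold peak classification with
#' search-back. Signal and noise peak levels are initialised from the first
#' two seconds of the integrated signal; a 200 ms refractory period
#' suppresses double detections; when no peak is accepted for 1.66 times the
#' running average RR interval, the candidate list is re-scanned with the
#' threshold halved. Accepted peaks are refined to the local maximum of the
#' 5-15 Hz band-passed signal.
#'
#' @param ecg An [ecg_signal]; sampling rate >= 100 Hz and duration >= 10 s.
#' @return An object of class `rpeak_series`: list with `peaks` (strictly
#'   increasing 1-based sample indices) and `fs`. A flat or too-short signal
#'   yields zero peaks with a warning.
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans. Biomed. Eng. 32(3), 230-236.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_signal"))
  fs <- ecg$fs
  if (fs < 100) stop("sampling rate must be >= 100 Hz for QRS detection")
  x <- ecg$samples
  empty <- structure(list(peaks = integer(0), fs = fs), class = "rpeak_series")
  if (length(x) < 10 * fs || stats::sd(x) == 0) {
    warning("signal flat or shorter than 10 s; no peaks detected")
    return(empty)
  }

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  der <- signal::filter(signal::Ma(c(1, 2, 0, -2, -1) * fs / 8), bp)
  sq <- as.numeric(der)^2
  wlen <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 1))
  mwi[is.na(mwi)] <- 0

  refractory <- round(0.200 * fs)
  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) == -2) + 1L
  if (!length(cand)) return(empty)
  # collapse candidates closer than the refractory period, keep the larger
  keep <- logical(length(cand))
  last <- -Inf; last_i <- 0L
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refractory) {
      keep[i] <- TRUE; last <- cand[i]; last_i <- i
    } else if (mwi[cand[i]] > mwi[cand[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE; last <- cand[i]; last_i <- i
    }
  }
  cand <- cand[keep]

  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_avg <- NA_real_
  recent_rr <- numeric(0)
  last_peak <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]; v <- mwi[p]
    accepted <- FALSE
    if (v > thr1 && p - last_peak >= refractory) {
      accepted <- TRUE
      spki <- 0.125 * v + 0.875 * spki
    } else if (!is.na(rr_avg) && p - last_peak > 1.66 * rr_avg) {
      # search-back: re-examine skipped candidates with the lower threshold
      back <- cand[cand > last_peak + refractory & cand <= p]
      back <- back[mwi[back] > thr1 / 2]
      if (length(back)) {
        p <- back[which.max(mwi[back])]; v <- mwi[p]
        accepted <- TRUE
        spki <- 0.25 * v + 0.75 * spki
      }
    }
    if (accepted) {
      if (is.finite(last_peak)) {
        recent_rr <- c(recent_rr, p - last_peak)
        if (length(recent_rr) > 8) recent_rr <- recent_rr[-1]
        rr_avg <- mean(recent_rr)
      }
      peaks <- c(peaks, p)
      last_peak <- p
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  if (!length(peaks)) return(empty)

  # refine to the local maximum of the band-passed signal; the integrator
  # delays peaks by roughly half its window plus the derivative delay
  halfwin <- as.integer(round(0.150 * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p) - halfwin); hi <- min(length(bp), as.integer(p))
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  refined <- refined[c(TRUE, diff(refined) >= refractory)]
  structure(list(peaks = refined, fs = fs), class = "rpeak_series")
}

#' R-peak series container
#'
#' @param peaks Strictly increasing 1-based sample indices of R-wave peaks.
#' @param fs Sampling rate, Hz.
#' @return An object of class `rpeak_series`.
#' @export
rpeak_series <- function(peaks, fs) {
  peaks <- as.integer(peaks)
  if (length(peaks) > 1 && any(diff(peaks) <= 0)) {
    stop("'peaks' must be strictly increasing")
  }
  if (fs <= 0) stop("'fs' must be positive")
  structure(list(peaks = peaks, fs = fs), class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks @ %g Hz\n", length(x$peaks), x$fs))
  invisible(x)
}

#' RR intervals from detected R peaks
#'
#' @param peaks An `rpeak_series` with at least two peaks.
#' @return An [rr_series] (ms) of length `length(peaks) - 1`, origin
#'   `"measured"`.
#' @examples
#' pk <- structure(list(peaks = c(1L, 126L, 251L), fs = 125), class = "rpeak_series")
#' compute_rr(pk)$rr  # 1000 1000
#' @export
compute_rr <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$peaks) < 2L) stop("at least two peaks are required")
  rr_series(diff(peaks$peaks) / peaks$fs * 1000, origin = "measured")
}

#' Flag artifact / ectopic beats by local-median deviation
#'
#' A beat is flagged when its RR interval deviates from the median of a
#' centred window of neighbouring beats by more than `rel_threshold` in
#' relative terms. The window median is computed with a running median
#' (`stats::runmed`), median end rule at the edges.
#'
#' @param rr An [rr_series].
#' @param rel_threshold Relative deviation threshold (default 0.2, i.e. 20%).
#' @param window Centred window length in beats (odd; default 11).
#' @return The [rr_series] with its `mask` filled in.
#' @export
flag_artifacts <- function(rr, rel_threshold = 0.2, window = 11L) {
  stopifnot(inherits(rr, "rr_series"))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(rr$rr)
  med <- if (n >= 3L) {
    stats::runmed(rr$rr, k = min(window, n - (1 - n %% 2)), endrule = "median")
  } else rep(stats::median(rr$rr), n)
  mask <- abs(rr$rr - med) / med > rel_threshold
  rr_series(rr$rr, mask = mask, origin = rr$origin)
}

#' Correct flagged beats by cubic-spline interpolation
#'
#' Replaces every flagged RR value with the natural cubic spline through the
#' unflagged beats (beat index as abscissa); unflagged beats are returned
#' unchanged and the origin is set to `"corrected"`. A flagged run covering
#' more than half of the series triggers an uncorrectable-segment warning
#' (the interpolation is still performed).
#'
#' @param rr An [rr_series] whose mask has been computed.
#' @return A corrected [rr_series] with an all-clear mask.
#' @export
correct_artifacts <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$rr)
  if (!any(rr$mask)) {
    return(rr_series(rr$rr, origin = "corrected"))
  }
  runs <- rle(rr$mask)
  if (max(runs$lengths[runs$values]) > n / 2) {
    warning("flagged run longer than half the series; correction unreliable")
  }
  good <- which(!rr$mask)
  if (length(good) < 2L) stop("too few unflagged beats to interpolate")
  out <- rr$rr
  out[rr$mask] <- stats::spline(good, rr$rr[good], xout = which(rr$mask),
                                method = "natural")$y
  out <- pmax(out, min(rr$rr[good]) * 0.25)  # keep intervals positive
  rr_series(out, origin = "corrected")
}

#' Quality-control exclusion decision
#'
#' A recording is excluded from analysis when the fraction of flagged
#' (artifact or ectopic) beats exceeds `max_artifact_fraction`; the bound is
#' strict, so exactly 20% flagged is kept under the default.
#'
#' @param rr An [rr_series] whose mask has been computed.
#' @param max_artifact_fraction Maximum tolerated flagged fraction
#'   (default 0.20).
#' @return List with `exclude` (logical), `fraction` and `n_flagged`.
#' @export
qc_exclude <- function(rr, max_artifact_fraction = 0.20) {
  stopifnot(inherits(rr, "rr_series"))
  frac <- mean(rr$mask)
  list(exclude = frac > max_artifact_fraction,
       fraction = frac, n_flagged = sum(rr$mask))
}

#' Extract the pre-awakening (hypnopompic) window
#'
#' Returns the beats whose cumulative time falls in the half-open interval
#' `[wake_time - window, wake_time)`, i.e. the final `window` seconds of
#' sleep before awakening (default one hour). The recording is assumed to
#' start at time 0.
#'
#' @param rr An [rr_series] covering the requested window.
#' @param wake_time Time of awakening, s from recording start.
#' @param window Window length, s (default 3600).
#' @return The windowed [rr_series].
#' @export
extract_hypnopompic_window <- function(rr, wake_time, window = 3600) {
  stopifnot(inherits(rr, "rr_series"))
  if (window <= 0) stop("'window' must be positive")
  total <- rr_duration(rr)
  if (wake_time - window < -1e-9) stop("window starts before the recording")
  if (wake_time > total + 1e-9) stop("recording ends before 'wake_time'")
  tt <- rr_times(rr)
  inside <- tt >= wake_time - window - 1e-9 & tt < wake_time - 1e-9
  if (!any(inside)) stop("no beats fall inside the requested window")
  rr_series(rr$rr[inside], mask = rr$mask[inside], origin = rr$origin)
}
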