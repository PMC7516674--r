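#' Split an RR series into consecutive fixed-duration segments
#'
#' Segments are defined on cumulative beat time: segment k collects the
#' beats whose cumulative time falls in `(k L, (k+1) L]` for segment length
#' L, so each beat belongs to exactly one segment. Only complete segments
#' are returned (`floor(duration / L)` of them); a one-hour series at the
#' default 300 s yields 12 five-minute segments.
#'
#' @param rr An [rr_series] of total duration >= `segment_length`.
#' @param segment_length Segment duration, s (default 300).
#' @return List of [rr_series] segments.
#' @export
segment_rr <- function(rr, segment_length = 300) {
  stopifnot(inherits(rr, "rr_series"))
  total <- rr_duration(rr)
  if (total < segment_length) stop("series shorter than one segment")
  n_seg <- floor(total / segment_length)
  tt <- rr_times(rr)
  idx <- ceiling((tt - 1e-9) / segment_length)  # 1-based segment of each beat
  lapply(seq_len(n_seg), function(k) {
    sel <- idx == k
    rr_series(rr$rr[sel], mask = rr$mask[sel], origin = rr$origin)
  })
}

# Welch power spectral density of an irregularly sampled tachogram:
# cubic-spline resampling to a uniform grid, linear detrend, Hann-windowed
# averaged periodogram. Returns freq (Hz) and psd (ms^2/Hz), one-sided.
tachogram_psd <- function(rr, resample_hz = 4, subwin_s = 120, overlap = 0.5) {
  tt <- rr_times(rr)
  if (length(tt) < 4L) stop("too few beats for spectral analysis")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  y <- stats::spline(tt, rr$rr, xout = grid, method = "fmm")$y
  y <- stats::lm.fit(cbind(1, seq_along(y)), y)$residuals  # linear detrend
  nwin <- min(length(y), round(subwin_s * resample_hz))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(y) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
  norm <- resample_hz * sum(w^2)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- y[s:(s + nwin - 1L)]
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / norm
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nwin)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * resample_hz / nwin, psd = psd * dbl)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Spectral band powers of a 5-minute RR segment
#'
#' Computes the one-sided power spectral density of the tachogram (cubic
#' spline resampled to 4 Hz, linearly detrended, Hann-windowed Welch
#' periodogram with 2-minute sub-windows at 50% overlap) and integrates it
#' by the trapezoidal rule over the standard short-term HRV bands: total
#' power 0.003-0.4 Hz, low frequency 0.04-0.15 Hz, high frequency
#' 0.15-0.4 Hz. The bin centred on the 0.15 Hz boundary is assigned to HF.
#' `HFnorm = HF / (LF + HF) x 100` (normalised units).
#'
#' @param segment An [rr_series] of at least 2 minutes.
#' @param resample_hz Resampling rate of the tachogram, Hz (default 4).
#' @return An object of class `spectral_bands`: named numeric vector with
#'   `TP`, `LF`, `HF` (ms^2) and `HFnorm` (n.u.).
#' @export
band_powers <- function(segment, resample_hz = 4) {
  stopifnot(inherits(segment, "rr_series"))
  if (rr_duration(segment) < 120) stop("segment shorter than 2 minutes")
  sp <- tachogram_psd(segment, resample_hz = resample_hz)
  band <- function(lo, hi, lo_open = FALSE) {
    sel <- if (lo_open) sp$freq > lo & sp$freq <= hi else sp$freq >= lo & sp$freq <= hi
    trapz(sp$freq[sel], sp$psd[sel])
  }
  tp <- band(0.003, 0.4)
  lf <- {  # LF owns [0.04, 0.15) -- the 0.15 Hz bin belongs to HF
    sel <- sp$freq >= 0.04 & sp$freq < 0.15
    trapz(sp$freq[sel], sp$psd[sel])
  }
  hf <- band(0.15, 0.4)
  hfnorm <- if (lf + hf > 0) hf / (lf + hf) * 100 else 0
  structure(c(TP = tp, LF = lf, HF = hf, HFnorm = hfnorm),
            class = "spectral_bands")
}

#' @export
print.spectral_bands <- function(x, ...) {
  cat(sprintf("<spectral_bands> TP %.1f  LF %.1f  HF %.1f ms^2, HFnorm %.1f n.u.\n",
              x["TP"], x["LF"], x["HF"], x["HFnorm"]))
  invisible(x)
}

#' Average spectral bands over segments
#'
#' Field-wise arithmetic mean over a list of per-segment band-power vectors;
#' `HFnorm` is averaged as the mean of the per-segment normalised values.
#'
#' @param bands Non-empty list of `spectral_bands`.
#' @return A `spectral_bands` vector of means.
#' @export
average_band_powers <- function(bands) {
  if (!length(bands)) stop("empty band list")
  m <- do.call(rbind, lapply(bands, unclass))
  structure(colMeans(m), class = "spectral_bands")
}

#' SDNN: standard deviation of all RR intervals
#'
#' Sample standard deviation (n - 1 denominator) of the full series, ms.
#'
#' @param rr An [rr_series] or numeric vector with >= 2 beats.
#' @return SDNN in ms.
#' @export
sdnn <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2L) stop("at least two beats required")
  stats::sd(x)
}

#' RMSSD: root mean square of successive RR differences
#'
#' @param rr An [rr_series] or numeric vector with >= 2 beats.
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2L) stop("at least two beats required")
  sqrt(mean(diff(x)^2))
}
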