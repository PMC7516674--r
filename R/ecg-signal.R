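#' ECG signal container
#'
#' @param samples Numeric vector of ECG amplitudes (mV).
#' @param fs Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `ecg_signal`.
#' @examples
#' ecg <- ecg_signal(sin(2 * pi * 1 * seq(0, 10, by = 1 / 125)), fs = 125)
#' @export
ecg_signal <- function(samples, fs, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) stop("ECG samples must be finite")
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read an ECG trace from single-column delimited text
#'
#' Expects one amplitude per line; the sampling rate is taken from a
#' `# fs: <Hz>` header line if present, else from the `fs` argument.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz, used when the file has no `# fs:` header.
#' @return An [ecg_signal].
#' @export
read_ecg <- function(path, fs = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("^# fs:", hdr, value = TRUE)
  if (length(fs_line)) fs <- as.numeric(trimws(sub("# fs:", "", fs_line[1], fixed = TRUE)))
  if (is.null(fs)) stop("sampling rate not found in file header; supply 'fs'")
  ecg_signal(as.numeric(lines[!startsWith(lines, "#")]), fs = fs)
}
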