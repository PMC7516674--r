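#' RR-interval series
#'
#' The central signal type of the package: an ordered sequence of RR intervals
#' (the time, in milliseconds, between successive ECG R-wave peaks) together
#' with a logical artifact mask of the same length and an origin annotation.
#'
#' @param rr Numeric vector of RR intervals in milliseconds. Must be strictly
#'   positive and finite.
#' @param mask Logical vector of the same length as `rr`; `TRUE` marks beats
#'   flagged as artifacts or ectopic. Defaults to all `FALSE`.
#' @param origin One of `"measured"`, `"corrected"`, `"synthetic"`.
#'
#' @return An object of class `rr_series`: a list with elements `rr`, `mask`
#'   and `origin`.
#'
#' @examples
#' rr <- rr_series(c(812, 798, 805, 820))
#' rr_duration(rr)
#' @export
rr_series <- function(rr, mask = NULL, origin = c("measured", "corrected", "synthetic")) {
  origin <- match.arg(origin)
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("'rr' must contain at least one interval")
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be finite and strictly positive")
  }
  if (is.null(mask)) mask <- rep(FALSE, length(rr))
  mask <- as.logical(mask)
  if (length(mask) != length(rr)) stop("'mask' must have the same length as 'rr'")
  if (anyNA(mask)) stop("'mask' must not contain NA")
  structure(list(rr = rr, mask = mask, origin = origin), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d beats, %.1f s, mean RR %.1f ms, %d flagged (%.1f%%), origin: %s\n",
    length(x$rr), sum(x$rr) / 1000, mean(x$rr), sum(x$mask),
    100 * mean(x$mask), x$origin
  ))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

#' Total duration of an RR series
#'
#' @param rr An [rr_series].
#' @return Duration in seconds (sum of intervals / 1000).
#' @export
rr_duration <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  sum(rr$rr) / 1000
}

#' Cumulative beat times of an RR series
#'
#' Beat `i` is placed at the end of its interval, so the first beat time is
#' `rr[1]/1000` seconds and the last equals the total duration.
#'
#' @param rr An [rr_series].
#' @return Numeric vector of beat times in seconds.
#' @export
rr_times <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  cumsum(rr$rr) / 1000
}

as_rr_series <- function(x, origin = "measured") {
  if (inherits(x, "rr_series")) x else rr_series(x, origin = origin)
}

#' Write / read RR series as delimited text
#'
#' The on-disk format is a tab-separated table with columns `beat`, `rr_ms`
#' and `artifact` (0/1), plus a `# origin:` comment line.
#'
#' @param rr An [rr_series].
#' @param path File path.
#' @return `write_rr` returns `path` invisibly; `read_rr` returns an
#'   [rr_series].
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin: %s", rr$origin), con)
  utils::write.table(
    data.frame(beat = seq_along(rr$rr), rr_ms = rr$rr, artifact = as.integer(rr$mask)),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  first <- readLines(path, n = 1L)
  origin <- "measured"
  if (startsWith(first, "# origin:")) {
    origin <- trimws(sub("# origin:", "", first, fixed = TRUE))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  rr_series(tab$rr_ms, mask = tab$artifact != 0, origin = origin)
}
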