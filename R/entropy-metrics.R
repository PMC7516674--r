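#' Coarse-grain a time series
#'
#' Averages consecutive non-overlapping windows of `scale` points, the first
#' step of multiscale entropy. The output has `floor(length(x) / scale)`
#' points; trailing points that do not fill a window are dropped.
#'
#' @param x Numeric vector.
#' @param scale Integer scale factor (>= 1).
#' @return Numeric vector of window means.
#' @examples
#' coarse_grain(c(3, 6, 9, 3, 6, 9), 3)  # c(6, 6)
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("'scale' must be >= 1")
  n <- length(x)
  if (scale > n) stop("'scale' exceeds series length")
  if (scale == 1L) return(as.numeric(x))
  nw <- n %/% scale
  colMeans(matrix(x[seq_len(nw * scale)], nrow = scale))
}

#' Sample entropy
#'
#' SampEn(m, r) is the negative natural log of the conditional probability
#' that two sequences matching for `m` points (Chebyshev distance <= `r`,
#' self-matches excluded) also match for `m + 1` points. When no template
#' pair matches at length m (or none extends), the statistic is undefined and
#' `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param x Numeric vector, length > `m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance, in the units of `x`. Typically `0.15 * sd(x)`.
#' @return A single numeric value (>= 0), or flagged `NA` when undefined.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(300), m = 2, r = 0.15 * sd(rnorm(300)))
#' @export
sample_entropy <- function(x, m = 2L, r) {
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  if (!is.numeric(r) || length(r) != 1L || r < 0) stop("'r' must be a single value >= 0")
  x <- as.numeric(x)
  if (length(x) <= m + 1L) stop("series too short for the requested embedding dimension")
  cnt <- .sampen_counts(x, m, r)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(A / B)
}

#' Multiscale sample entropy profile
#'
#' Computes SampEn on coarse-grained versions of an RR series for scale
#' factors 1..`max_scale`. The tolerance is fixed once as
#' `r_coeff * sd(original series)` and reused at every scale (no per-scale
#' renormalisation), so the profile reflects how matching probability changes
#' as averaging removes fast variability.
#'
#' @param rr An [rr_series] or numeric vector (ms).
#' @param m Embedding dimension (default 2).
#' @param r_coeff Tolerance coefficient applied to the SD of the original
#'   series (default 0.15).
#' @param max_scale Largest scale factor (default 10).
#' @param mpe_m Embedding dimension of the tied-rank permutation entropy
#'   (default 4).
#' @return An object of class `entropy_profile`: list with `mse` (named
#'   vector MSE1..MSE<max_scale>), `mpe`, and the parameters used. Undefined
#'   scales are `NA`.
#' @seealso [sample_entropy()], [modified_permutation_entropy()]
#' @export
mse_profile <- function(rr, m = 2L, r_coeff = 0.15, max_scale = 10L, mpe_m = 4L) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  max_scale <- as.integer(max_scale)
  if (max_scale < 1L) stop("'max_scale' must be >= 1")
  if (length(x) %/% max_scale <= m + 1L) {
    stop("series too short: coarse-grained length at the largest scale must exceed m + 1")
  }
  r <- r_coeff * stats::sd(x)
  mse <- vapply(seq_len(max_scale), function(tau) {
    as.numeric(sample_entropy(coarse_grain(x, tau), m = m, r = r))
  }, numeric(1))
  names(mse) <- paste0("MSE", seq_len(max_scale))
  structure(
    list(mse = mse, mpe = modified_permutation_entropy(x, m = mpe_m),
         m = m, r = r, r_coeff = r_coeff, max_scale = max_scale, mpe_m = mpe_m),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> m = %d, r = %.3f ms, MPE(m = %d) = %.3f bits\n",
              x$m, x$r, x$mpe_m, x$mpe))
  print(round(x$mse, 3))
  invisible(x)
}

# Dense tied-rank pattern of one embedded vector: equal values share a symbol.
tied_rank_pattern <- function(v) {
  paste(match(v, sort(unique(v))), collapse = "")
}

#' Modified (tied-rank) permutation entropy
#'
#' Ordinal-pattern entropy in which equal values in an embedded vector are
#' assigned equal rank symbols, instead of being broken by order of
#' appearance as in the original permutation entropy. This makes the measure
#' robust to the heavy value ties produced by coarse amplitude quantisation
#' (e.g. RR intervals measured on a fixed sampling grid). The series is
#' embedded with delay 1 into overlapping vectors of length `m`; the entropy
#' is the Shannon entropy, in bits, of the empirical pattern distribution.
#'
#' For `m = 4` there are 75 possible tied-rank patterns (the ordered set
#' partitions of 4 items), so the value lies in `[0, log2(75)]`; a long
#' tie-free i.i.d. series approaches `log2(24)`.
#'
#' @param x Numeric vector, length >= `m`.
#' @param m Embedding dimension (default 4).
#' @return Entropy in bits (>= 0).
#' @examples
#' modified_permutation_entropy(1:100)          # single pattern: 0
#' modified_permutation_entropy(rep(1, 50), 4)  # all tied: 0
#' @export
modified_permutation_entropy <- function(x, m = 4L) {
  m <- as.integer(m)
  if (m < 2L) stop("'m' must be >= 2")
  x <- as.numeric(x)
  n <- length(x)
  if (n < m) stop("series shorter than the embedding dimension")
  idx <- seq_len(n - m + 1L)
  patterns <- vapply(idx, function(i) tied_rank_pattern(x[i:(i + m - 1L)]), character(1))
  p <- tabulate(factor(patterns)) / length(patterns)
  -sum(p * log2(p))
}
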