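#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the sample, with the p-value drawn from the Lilliefors
#' null distribution (via the `nortest` package implementation).
#'
#' @param x Numeric sample, n >= 5.
#' @return List with `statistic` (D) and `p.value`.
#' @export
lilliefors_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("at least 5 observations required")
  if (stats::sd(x) == 0) return(list(statistic = 1, p.value = 0))
  res <- nortest::lillie.test(x)
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum gap between the empirical CDFs of two samples, with the
#' asymptotic p-value.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `D` and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p.value = unname(res$p.value))
}

#' Jensen-Shannon divergence between two samples
#'
#' Histograms both samples on shared bins spanning the pooled range
#' (Freedman-Diaconis bin width, at least `min_bins` bins), smooths
#' zero-count cells with machine-epsilon mass, normalises, and returns
#' `JSD = KL(P||M)/2 + KL(Q||M)/2` with `M = (P + Q)/2` and base-2
#' logarithms, so the value lies in `[0, 1]`: 0 for identical
#' distributions, 1 for fully disjoint ones.
#'
#' @param x,y Non-empty numeric samples.
#' @param bins Number of bins; `NULL` (default) chooses by Freedman-Diaconis
#'   on the pooled sample.
#' @param min_bins Lower bound on the bin count (default 10).
#' @return JSD in bits, in `[0, 1]`.
#' @export
jensen_shannon_divergence <- function(x, y, bins = NULL, min_bins = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- c(x, y)
  rng <- range(pooled)
  if (is.null(bins)) {
    iqr <- stats::IQR(pooled)
    h <- 2 * iqr / length(pooled)^(1 / 3)
    bins <- if (h > 0 && diff(rng) > 0) max(min_bins, ceiling(diff(rng) / h)) else min_bins
  }
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- graphics::hist(x, breaks = brk, plot = FALSE)$counts
  q <- graphics::hist(y, breaks = brk, plot = FALSE)$counts
  p <- p + .Machine$double.eps; q <- q + .Machine$double.eps
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(a * log2(a / b))
  (kl(p, m) + kl(q, m)) / 2
}

summarise_continuous <- function(x, normal) {
  if (normal) {
    sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f[%.1f,%.1f]", q[2], q[1], q[3])
  }
}

#' Between-group comparison of one cohort variable
#'
#' Categorical variables (factors, characters, logicals) are compared with a
#' chi-square test on the contingency table. Continuous variables are first
#' gated through the Lilliefors normality test in each group (alpha = 0.05):
#' a t-test is used when both groups look normal, a Mann-Whitney
#' (Wilcoxon rank-sum) test otherwise. Summaries mirror the usual clinical
#' reporting convention: category percentages, mean +/- SD for normal
#' variables, median [Q1, Q3] otherwise.
#'
#' @param table Data.frame with a group column and the variable.
#' @param variable Name of the variable to compare.
#' @param group_col Name of the grouping column (two levels; default
#'   `"group"`).
#' @return An object of class `group_comparison`: list with `variable`,
#'   `test` (`"chi-square"`, `"t"` or `"mann-whitney"`), `statistic`,
#'   `p.value` and per-group `summaries`.
#' @export
compare_groups <- function(table, variable, group_col = "group") {
  if (!variable %in% names(table)) stop("unknown variable: ", variable)
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2L) stop("grouping column must have exactly two levels")
  if (any(tabulate(g, 2L) == 0L)) stop("both groups must be non-empty")
  x <- table[[variable]]
  categorical <- is.factor(x) || is.character(x) || is.logical(x)
  if (categorical) {
    tab <- base::table(x, g)
    res <- suppressWarnings(stats::chisq.test(tab))
    summaries <- lapply(levels(g), function(lev) {
      prop <- prop.table(base::table(x[g == lev]))
      paste(sprintf("%s %.1f%%", names(prop), 100 * prop), collapse = " / ")
    })
    out <- list(variable = variable, test = "chi-square",
                statistic = unname(res$statistic), p.value = res$p.value)
  } else {
    xs <- split(as.numeric(x), g)
    normal <- vapply(xs, function(v) lilliefors_test(v)$p.value >= 0.05, logical(1))
    if (all(normal)) {
      res <- stats::t.test(xs[[1]], xs[[2]])
      out <- list(variable = variable, test = "t",
                  statistic = unname(res$statistic), p.value = res$p.value)
    } else {
      res <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]]))
      out <- list(variable = variable, test = "mann-whitney",
                  statistic = unname(res$statistic), p.value = res$p.value)
    }
    summaries <- lapply(seq_along(xs), function(i) {
      summarise_continuous(xs[[i]], all(normal))
    })
  }
  names(summaries) <- levels(g)
  out$summaries <- summaries
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s; %s test, p = %.4g\n", x$variable,
              x$summaries[[1]], x$summaries[[2]], x$test, x$p.value))
  invisible(x)
}

#' Group-comparison report over many variables
#'
#' Runs [compare_groups()] for each variable and collects a report table in
#' the style of a clinical baseline-characteristics table.
#'
#' @param table Data.frame with a group column.
#' @param variables Character vector of variable names; defaults to all
#'   columns except the group column and `id`.
#' @param group_col Grouping column name.
#' @return Data.frame with one row per variable: test, statistic, p-value
#'   and the two group summaries.
#' @export
cohort_comparison_table <- function(table, variables = NULL, group_col = "group") {
  variables <- variables %||% setdiff(names(table), c(group_col, "id"))
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(table, v, group_col)
    data.frame(variable = v, test = cmp$test,
               statistic = cmp$statistic, p.value = cmp$p.value,
               group1 = cmp$summaries[[1]], group2 = cmp$summaries[[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[5:6] <- names(compare_groups(table, variables[1], group_col)$summaries)
  out
}

#' Distribution-similarity report between a subset and its parent sample
#'
#' For each requested continuous variable, computes the two-sample K-S
#' statistic and p-value plus the Jensen-Shannon divergence between the
#' subset and the full sample. Used to check that an under-sampled control
#' group still represents the population it was drawn from.
#'
#' @param subset,parent Data.frames with the same columns.
#' @param variables Continuous variable names.
#' @return Data.frame with columns `variable`, `D`, `ks_p`, `jsd`.
#' @export
similarity_report <- function(subset, parent, variables) {
  rows <- lapply(variables, function(v) {
    ks <- ks_two_sample(subset[[v]], parent[[v]])
    data.frame(variable = v, D = ks$D, ks_p = ks$p.value,
               jsd = jensen_shannon_divergence(subset[[v]], parent[[v]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
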