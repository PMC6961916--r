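#' Paired Wilcoxon signed-rank test between two regions
#'
#' Compares per-gene intensities of two regions with the signed-rank test:
#' zero differences are dropped, tied absolute differences receive average
#' ranks, and V is the sum of ranks of the positive differences. The p-value
#' is two-sided, from the exact distribution when 25 or fewer nonzero
#' differences remain and there are no ties, otherwise from the normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric vectors of equal length, paired by gene.
#' @param exact_max_n Largest n for which the exact distribution is used.
#' @return A [test_result()] with statistic `V`; `n` is the number of nonzero
#'   differences.
#' @export
wilcoxon_paired <- function(x, y, exact_max_n = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    stop("all paired differences are zero; test undefined", call. = FALSE)
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= exact_max_n && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y,
      paired = TRUE, exact = exact, correct = TRUE,
      alternative = "two.sided"
    )
  )
  test_result(
    method = paste0(
      "Wilcoxon signed rank (",
      if (exact) "exact" else "normal approximation", ")"
    ),
    statistic_name = "V", statistic = ht$statistic,
    p_value = ht$p.value, n = length(nz)
  )
}

#' Chi-square goodness-of-fit test against equal proportions
#'
#' Tests whether category counts (e.g. genes exclusively expressed per brain
#' region) are equally distributed: `X² = sum((obs - exp)² / exp)` with equal
#' expected counts, `df = k - 1`, no continuity correction.
#'
#' @param counts Non-negative integer vector, length >= 2.
#' @return A [test_result()] with statistic `X-squared`.
#' @export
chisq_equal <- function(counts) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  if (sum(counts) == 0) {
    stop("total count is zero; test undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts))
  test_result(
    method = "chi-square goodness of fit (equal proportions)",
    statistic_name = "X-squared", statistic = ht$statistic,
    df = ht$parameter, p_value = ht$p.value, n = sum(counts)
  )
}

#' Exact binomial test on detected-gene counts of two regions
#'
#' Tests whether the numbers of genes detected in two regions differ, as an
#' exact two-sided binomial test of `k1` successes in `k1 + k2` trials
#' against success probability 0.5. (This treats each gene detected in
#' exactly one of the two regions as a Bernoulli trial; the construction is
#' stated in the output method label.)
#'
#' @param k_region1,k_region2 Non-negative detected counts.
#' @return A [test_result()]; the reported statistic is `k = k_region1`.
#' @export
binomial_detected <- function(k_region1, k_region2) {
  stopifnot(k_region1 >= 0, k_region2 >= 0)
  n <- k_region1 + k_region2
  if (n == 0) stop("both counts are zero; test undefined", call. = FALSE)
  ht <- stats::binom.test(k_region1, n, p = 0.5, alternative = "two.sided")
  test_result(
    method = "exact binomial (k1 of k1 + k2 vs p = 0.5)",
    statistic_name = "k", statistic = k_region1,
    p_value = ht$p.value, n = n
  )
}

#' Case-bootstrap correlation of normalized expression between regions
#'
#' Pearson correlation of arcsine-square-root transformed normalized values
#' (`x -> asin(sqrt(x / 100))`, the variance-stabilizing transform for
#' percentages), with a case bootstrap: genes (rows) are resampled with
#' replacement `reps` times and a percentile confidence interval is taken
#' from the replicate correlations.
#'
#' @param a,b Numeric vectors of normalized values in `[0, 100]`, paired by
#'   gene, length >= 3.
#' @param reps Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `hippaxis_bootci`: `estimate`, `lower`,
#'   `upper`, `conf`, `reps`, `n`, `method`.
#' @export
bootstrap_correlation <- function(a, b, reps = 10000L, seed = 1L,
                                  conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 3, reps >= 1)
  if (any(a < 0 | a > 100 | b < 0 | b > 100)) {
    stop("normalized values must lie in [0, 100]", call. = FALSE)
  }
  ta <- asin(sqrt(a / 100))
  tb <- asin(sqrt(b / 100))
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) {
    stop("zero variance after transform; correlation undefined",
      call. = FALSE
    )
  }
  est <- stats::cor(ta, tb)
  bt <- with_seed(seed, {
    boot::boot(
      data = cbind(ta, tb),
      statistic = function(d, i) suppressWarnings(stats::cor(d[i, 1], d[i, 2])),
      R = reps
    )
  })
  reps_ok <- bt$t[is.finite(bt$t)]
  qs <- stats::quantile(reps_ok, c((1 - conf) / 2, 1 - (1 - conf) / 2),
    names = FALSE
  )
  structure(
    list(
      estimate = est, lower = qs[1], upper = qs[2], conf = conf,
      reps = as.integer(reps), n = length(a),
      method = "Pearson on arcsine-sqrt values, case bootstrap percentile CI"
    ),
    class = "hippaxis_bootci"
  )
}

#' @export
print.hippaxis_bootci <- function(x, ...) {
  cat(sprintf(
    "r = %.4f, %g%% percentile CI [%.4f, %.4f] (%d replicates, n = %d)\n",
    x$estimate, 100 * x$conf, x$lower, x$upper, x$reps, x$n
  ))
  invisible(x)
}

#' Dunn-Sidak corrected critical p-value
#'
#' Per-comparison critical level controlling the family-wise error rate over
#' `m` independent comparisons: `1 - (1 - alpha)^(1/m)`. For alpha = 0.05
#' this gives 0.0169 for three and 0.00851 for six comparisons.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return The corrected critical p-value.
#' @examples
#' dunn_sidak(0.05, 3)
#' dunn_sidak(0.05, 6)
#' @export
dunn_sidak <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  1 - (1 - alpha)^(1 / m)
}

#' Paired t test between two regions
#'
#' Standard paired t test on per-gene differences, two-sided,
#' `df = n - 1`. Used for pairwise comparison of the hippocampal subfields.
#'
#' @param x,y Numeric vectors of equal length >= 2, paired by gene.
#' @return A [test_result()] with statistic `t`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2) stop("need at least two pairs", call. = FALSE)
  if (stats::sd(x - y) == 0) {
    stop("zero variance of differences; test undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  test_result(
    method = "paired t", statistic_name = "t", statistic = ht$statistic,
    df = ht$parameter, p_value = ht$p.value, n = length(x)
  )
}
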