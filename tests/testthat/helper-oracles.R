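# Independent reference implementations used as oracles. These are written
# from the textbook definitions (rank sums, sign-flip enumeration, closed-form
# statistics with distribution functions) and never call the package's own
# code paths.

oracle_wilcoxon_v <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_wilcoxon_p_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  min(1, 2 * min(lower, upper))
}

# Normal approximation with continuity correction and tie correction,
# matching the classical large-sample signed-rank test.
oracle_wilcoxon_p_normal <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

oracle_chisq_equal <- function(counts) {
  k <- length(counts)
  e <- sum(counts) / k
  stat <- sum((counts - e)^2 / e)
  list(stat = stat, df = k - 1, p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Exact two-sided binomial p: sum of all outcome probabilities not exceeding
# the observed one (the standard small-p-values definition for p0 = 0.5).
oracle_binom_p <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

oracle_welch <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_student <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]
  b <- tab[1, 2]
  cc <- tab[2, 1]
  d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# Build a delta table by hand (bypassing compute_delta) for resampling tests.
make_delta <- function(values, groups) {
  structure(
    data.frame(
      gene = sprintf("g%02d", seq_along(values)),
      dg = NA, mean_ca = NA, offset = 1, delta = values,
      group = groups, stringsAsFactors = FALSE
    ),
    class = c("hippaxis_delta", "data.frame")
  )
}
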