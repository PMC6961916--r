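#' Per-gene DG-vs-CA log ratio (delta)
#'
#' For each gene the CA value is the arithmetic mean of the CA1, CA2 and CA3
#' values; a small offset (1 or 2) is added to both sides to accommodate
#' zeros; and the log ratio is
#' `delta = log(DG + offset) - log(meanCA + offset)` (base 10 by default).
#' Positive delta marks DG enrichment, negative delta CA enrichment. Group
#' conclusions (sign of the group difference, permutation significance) are
#' expected to be stable across offsets 1 and 2.
#'
#' @param profiles Data frame with `gene` and subfield columns `CA1`, `CA2`,
#'   `CA3`, `DG` (normalized percentages or raw intensities).
#' @param groups Optional data frame `gene`, `group` with labels `"A"`
#'   (challenge) and `"B"` (sufficiency); genes without a label get `NA`.
#' @param offset Offset added before log transformation, 1 or 2.
#' @param log_base Logarithm base (default 10).
#' @param ca_fields Subfields averaged into the CA value (default CA1-CA3).
#' @return Data frame of class `hippaxis_delta`: `gene`, `dg`, `mean_ca`,
#'   `offset`, `delta`, `group`. Rows with missing subfield values are
#'   excluded; attribute `n_excluded` counts them.
#' @export
compute_delta <- function(profiles, groups = NULL, offset = 1,
                          log_base = 10,
                          ca_fields = c("CA1", "CA2", "CA3")) {
  need <- c(ca_fields, "DG")
  if (!all(need %in% names(profiles))) {
    stop(
      "missing subfield columns: ",
      paste(setdiff(need, names(profiles)), collapse = ", "),
      call. = FALSE
    )
  }
  if (!offset %in% c(1, 2)) stop("offset must be 1 or 2", call. = FALSE)
  ok <- stats::complete.cases(profiles[, need])
  excluded <- sum(!ok)
  if (excluded > 0) {
    message(excluded, " gene(s) excluded from delta (missing subfield values)")
  }
  d <- profiles[ok, ]
  mean_ca <- rowMeans(d[, ca_fields, drop = FALSE])
  delta <- log(d$DG + offset, log_base) - log(mean_ca + offset, log_base)
  out <- data.frame(
    gene = d$gene, dg = d$DG, mean_ca = mean_ca, offset = offset,
    delta = delta, group = NA_character_, stringsAsFactors = FALSE
  )
  if (!is.null(groups)) {
    out$group <- groups$group[match(out$gene, groups$gene)]
    out$group[!out$group %in% c("A", "B")] <- NA
  }
  structure(out,
    n_excluded = excluded, log_base = log_base,
    class = c("hippaxis_delta", "data.frame")
  )
}

delta_groups <- function(delta) {
  a <- delta$delta[delta$group %in% "A"]
  b <- delta$delta[delta$group %in% "B"]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups A and B must be non-empty", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Welch's t test between challenge and sufficiency delta values
#'
#' Unequal-variance t test with Welch-Satterthwaite fractional degrees of
#' freedom, two-sided.
#'
#' @param delta_a,delta_b Delta values of groups A and B (length >= 2 each).
#' @return A [test_result()] with statistic `t` and fractional `df`.
#' @export
welch_t <- function(delta_a, delta_b) {
  stopifnot(length(delta_a) >= 2, length(delta_b) >= 2)
  if (stats::sd(delta_a) == 0 && stats::sd(delta_b) == 0) {
    stop("zero variance in both groups; test undefined", call. = FALSE)
  }
  ht <- stats::t.test(delta_a, delta_b,
    var.equal = FALSE,
    alternative = "two.sided"
  )
  test_result(
    method = "Welch two-sample t", statistic_name = "t",
    statistic = ht$statistic, df = ht$parameter, p_value = ht$p.value,
    n = length(delta_a) + length(delta_b)
  )
}

#' Two-stage permutation test of the group difference in mean delta
#'
#' Stage one computes the observed statistic: mean delta of group A minus
#' mean delta of group B. Stage two randomizes the group labels (preserving
#' group sizes), recomputes the difference, and repeats to build a null
#' distribution. The two-sided p-value is
#' `(1 + #\{|null| >= |observed|\}) / (reps + 1)`; with 12 or fewer genes the
#' label assignments are enumerated exhaustively instead (p is then the exact
#' fraction of assignments, the identity included, at least as extreme).
#'
#' @param delta A [compute_delta()] table with group labels.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed Integer seed for the Monte-Carlo path.
#' @param exhaustive_max Largest total group size for which assignments are
#'   enumerated exhaustively (default 12).
#' @return List of class `hippaxis_perm`: `observed`, `p_value`, `reps`,
#'   `method` (`"exhaustive"` or `"monte carlo"`), `seed`, `null_mean`,
#'   `null_sd`, `n_a`, `n_b`.
#' @export
permutation_test <- function(delta, reps = 10000L, seed = 1L,
                             exhaustive_max = 12L) {
  g <- delta_groups(delta)
  v <- c(g$a, g$b)
  n <- length(v)
  n_a <- length(g$a)
  observed <- mean(g$a) - mean(g$b)
  total_mean <- mean(v)
  # mean(A) - mean(B) is a function of the A-subset mean alone:
  # diff = (n / (n - n_a)) * (mean_A - total_mean) ... scaled form below
  diff_from_mean_a <- function(mean_a) {
    (mean_a - total_mean) * n / (n - n_a)
  }
  tol <- 1e-12 * max(1, abs(observed))
  if (n <= exhaustive_max) {
    idx <- utils::combn(n, n_a)
    null <- diff_from_mean_a(colMeans(matrix(v[idx], nrow = n_a)))
    p <- mean(abs(null) >= abs(observed) - tol)
    method <- "exhaustive"
    nrep <- ncol(idx)
  } else {
    null <- with_seed(seed, {
      vapply(
        seq_len(reps),
        function(i) diff_from_mean_a(mean(v[sample.int(n, n_a)])),
        numeric(1)
      )
    })
    p <- (1 + sum(abs(null) >= abs(observed) - tol)) / (reps + 1)
    method <- "monte carlo"
    nrep <- as.integer(reps)
  }
  structure(
    list(
      observed = observed, p_value = p, reps = nrep, method = method,
      seed = seed, null_mean = mean(null), null_sd = stats::sd(null),
      n_a = n_a, n_b = n - n_a
    ),
    class = "hippaxis_perm"
  )
}

#' @export
print.hippaxis_perm <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s, %d assignments): observed diff = %.4g, p = %.4g\n",
    x$method, x$reps, x$observed, x$p_value
  ))
  invisible(x)
}

#' Fold difference between challenge and sufficiency groups
#'
#' The between-group contrast on the ratio scale:
#' `base^(mean delta(A) - mean delta(B))`. Invariant to the log base used
#' consistently in [compute_delta()].
#'
#' @param delta A [compute_delta()] table with group labels.
#' @param log_base Base used for the delta values (default 10).
#' @return Positive fold difference.
#' @export
fold_difference <- function(delta, log_base = 10) {
  g <- delta_groups(delta)
  log_base^(mean(g$a) - mean(g$b))
}

#' Per-group enrichment fold
#'
#' The geometric-mean within-group DG/CA enrichment implied by the group
#' contrast under a symmetric design (group A DG-enriched and group B
#' CA-enriched by the same factor):
#' `base^((mean delta(A) - mean delta(B)) / 2)`, i.e. the square root of
#' [fold_difference()]. This is the quantity compared against a configured
#' per-group enrichment in recovery studies.
#'
#' @inheritParams fold_difference
#' @return Positive per-group fold.
#' @export
enrichment_fold <- function(delta, log_base = 10) {
  sqrt(fold_difference(delta, log_base))
}

#' DG-vs-CA axis analysis on RNA-seq (FPKM) profiles
#'
#' Cross-validation variant of the axis analysis: subfield FPKM values below
#' the detection floor (4 FPKM, the level equated to an undetectable
#' hybridization signal) are set to 0 — the floor itself is retained — CA
#' subfields are averaged, deltas are computed on `log(FPKM + offset)`, and
#' both the Welch t test and the permutation test are run on the group
#' labels.
#'
#' @param fpkm Data frame `gene` + subfield FPKM columns.
#' @param groups Data frame `gene`, `group` (`"A"`/`"B"`).
#' @param floor Detection floor in FPKM units (default 4; values strictly
#'   below are zeroed).
#' @param offset Offset for the log transform (1 or 2).
#' @param reps,seed Permutation-test parameters.
#' @param log_base Log base.
#' @return List: `delta` table, `welch` [test_result()], `permutation`
#'   [permutation_test()] result.
#' @export
fpkm_axis <- function(fpkm, groups, floor = 4, offset = 1, reps = 10000L,
                      seed = 1L, log_base = 10) {
  need <- c("CA1", "CA2", "CA3", "DG")
  if (!all(need %in% names(fpkm))) {
    stop(
      "missing subfield FPKM columns: ",
      paste(setdiff(need, names(fpkm)), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(as.matrix(fpkm[, need]) < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  floored <- fpkm
  for (f in need) floored[[f]] <- ifelse(floored[[f]] < floor, 0, floored[[f]])
  delta <- compute_delta(floored,
    groups = groups, offset = offset,
    log_base = log_base
  )
  g <- delta_groups(delta)
  list(
    delta = delta,
    welch = welch_t(g$a, g$b),
    permutation = permutation_test(delta, reps = reps, seed = seed)
  )
}
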