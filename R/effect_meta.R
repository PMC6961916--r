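#' Mean coded ligand effect per receptor group
#'
#' Effect codes summarize the literature-recorded action of each receptor's
#' ligand on a readout (long-term potentiation or neurogenesis): -1 inhibits,
#' 0 mixed/none, +1 promotes, `NA` unknown. Unknown codes are excluded; the
#' arithmetic mean of the remaining codes is reported per group with its n.
#'
#' @param effects Data frame `gene`, `group` (`"A"`/`"B"`), `ltp`,
#'   `neurogenesis` with codes -1/0/1/`NA`.
#' @param parameter `"ltp"` or `"neurogenesis"`.
#' @return Data frame: `group`, `mean_code`, `n`.
#' @export
group_mean_scores <- function(effects, parameter = c("ltp", "neurogenesis")) {
  parameter <- match.arg(parameter)
  codes <- effects[[parameter]]
  check_codes(codes)
  out <- do.call(rbind, lapply(c("A", "B"), function(g) {
    v <- codes[effects$group %in% g & !is.na(codes)]
    if (length(v) == 0) {
      stop("group ", g, " has no known codes; mean undefined", call. = FALSE)
    }
    data.frame(group = g, mean_code = mean(v), n = length(v))
  }))
  rownames(out) <- NULL
  out
}

check_codes <- function(codes) {
  if (!all(codes %in% c(-1, 0, 1, NA))) {
    stop("effect codes must be -1, 0, 1 or NA", call. = FALSE)
  }
}

#' Compare coded ligand effects between challenge and sufficiency groups
#'
#' Two tests of whether effect direction differs between groups A and B:
#' a Student's (pooled-variance) unpaired t test on the full codes (0
#' included, `NA` excluded), and a Pearson chi-square test without continuity
#' correction on the 2x2 table of inhibition (-1) versus stimulation (+1) by
#' group (0 and `NA` excluded, contrasting inhibition versus stimulation).
#' Both are two-sided. Either test can be undefined on degenerate data (zero
#' pooled variance; an empty 2x2 margin); the corresponding component then
#' carries the captured error condition while the other remains valid.
#'
#' @inheritParams group_mean_scores
#' @return List with components `t` and `chisq`, each a [test_result()] or,
#'   when undefined, the error condition.
#' @export
compare_groups <- function(effects, parameter = c("ltp", "neurogenesis")) {
  parameter <- match.arg(parameter)
  codes <- effects[[parameter]]
  check_codes(codes)
  a <- codes[effects$group %in% "A" & !is.na(codes)]
  b <- codes[effects$group %in% "B" & !is.na(codes)]

  t_res <- tryCatch(
    {
      if (length(a) < 2 || length(b) < 2) {
        stop("need >= 2 known codes per group", call. = FALSE)
      }
      pooled_df <- length(a) + length(b) - 2
      pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / pooled_df
      if (pooled_var == 0) {
        stop("zero pooled variance; t test undefined", call. = FALSE)
      }
      ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
      test_result(
        method = "Student unpaired t (pooled variance)",
        statistic_name = "t", statistic = ht$statistic, df = ht$parameter,
        p_value = ht$p.value, n = length(a) + length(b)
      )
    },
    error = function(e) e
  )

  chisq_res <- tryCatch(
    {
      sa <- a[a != 0]
      sb <- b[b != 0]
      tab <- rbind(
        A = c(inhibit = sum(sa == -1), promote = sum(sa == 1)),
        B = c(inhibit = sum(sb == -1), promote = sum(sb == 1))
      )
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        stop("empty margin in 2x2 table; chi-square undefined", call. = FALSE)
      }
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      test_result(
        method = "Pearson chi-square on 2x2 (inhibit vs promote, no correction)",
        statistic_name = "X-squared", statistic = ht$statistic,
        df = ht$parameter, p_value = ht$p.value, n = sum(tab)
      )
    },
    error = function(e) e
  )

  list(t = t_res, chisq = chisq_res)
}
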