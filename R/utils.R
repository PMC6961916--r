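#' Region vocabularies
#'
#' Fixed vocabularies for the three whole-brain regions (hippocampus, cortex,
#' cerebellum) and the four hippocampal subfields (CA1-CA3 and dentate gyrus)
#' used throughout the package.
#'
#' @format Character vectors.
#' @name region_vocab
NULL

#' @rdname region_vocab
#' @export
BRAIN_REGIONS <- c("HPC", "CX", "CB")

#' @rdname region_vocab
#' @export
HPC_SUBFIELDS <- c("CA1", "CA2", "CA3", "DG")

#' @rdname region_vocab
#' @export
ALL_REGIONS <- c(BRAIN_REGIONS, HPC_SUBFIELDS)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package flows through
# this helper so that stage-level substreams never perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage substream seed from a root seed
#'
#' Expands one root seed into independent, reproducible substreams, one per
#' named pipeline stage, by mixing the root seed with a stable polynomial
#' hash of the stage name. Keeps every derived seed in the 32-bit integer
#' range R requires.
#'
#' @param seed Integer root seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed, deterministic in `(seed, stage)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# Stable non-cryptographic hash of a character scalar; used to fingerprint
# configurations in run metadata.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 7
  for (k in utf8ToInt(x)) h <- (h * 131 + k) %% m
  sprintf("%08x", as.integer(h))
}

#' Construct a hypothesis-test result record
#'
#' Light container for the statistics the pipeline reports: method, named
#' statistic, optional (possibly fractional) degrees of freedom, p-value,
#' sample size and sidedness.
#'
#' @param method Character label for the test.
#' @param statistic_name One of `"V"`, `"t"`, `"X-squared"`, `"z"`, `"k"`.
#' @param statistic Numeric statistic value.
#' @param p_value p-value in `[0, 1]`.
#' @param n Sample size the test was computed on.
#' @param df Degrees of freedom, `NA` where not applicable.
#' @param sided `"two.sided"` throughout this package.
#' @return An object of class `hippaxis_test`.
#' @export
test_result <- function(method, statistic_name, statistic, p_value, n,
                        df = NA_real_, sided = "two.sided") {
  stopifnot(p_value >= 0, p_value <= 1, n >= 1)
  structure(
    list(
      method = method, statistic_name = statistic_name,
      statistic = unname(statistic), df = unname(df),
      p_value = unname(p_value), n = as.integer(n), sided = sided
    ),
    class = "hippaxis_test"
  )
}

#' @export
print.hippaxis_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(
    "  %s = %.6g%s, p = %.4g (%s, n = %d)\n",
    x$statistic_name, x$statistic,
    if (is.na(x$df)) "" else sprintf(", df = %.4g", x$df),
    x$p_value, x$sided, x$n
  ))
  invisible(x)
}

#' @export
as.data.frame.hippaxis_test <- function(x, ...) {
  data.frame(
    method = x$method, statistic = x$statistic_name, value = x$statistic,
    df = x$df, p_value = x$p_value, n = x$n, sided = x$sided,
    stringsAsFactors = FALSE
  )
}

# rbind a list of hippaxis_test objects into one results table.
bind_test_results <- function(results) {
  stopifnot(length(results) > 0)
  out <- do.call(rbind, lapply(results, as.data.frame))
  if (!is.null(names(results))) out <- cbind(comparison = names(results), out)
  rownames(out) <- NULL
  out
}
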