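# Score-stratified outcome tables and Pearson chi-square association tests.

#' Outcome rate stratified by score value
#'
#' One row per observed score value with the number of patients, the number
#' of events, and the event rate as a percentage rounded to one decimal
#' place (the precision at which such rates are conventionally reported).
#'
#' @param scored Data frame of a scored cohort (see [score_cohort()]).
#' @param score Name of the score column (e.g. `"smart"`).
#' @param outcome Name of the binary outcome column (e.g. `"died_7d"`).
#' @return Data frame with columns `score`, `n`, `events`, `rate`.
#' @export
stratified_rates <- function(scored, score, outcome) {
  scored <- as.data.frame(scored, stringsAsFactors = FALSE)
  for (col in c(score, outcome))
    if (!col %in% names(scored))
      stop("stratified_rates: no column named '", col, "' in the scored cohort",
           call. = FALSE)
  vals <- sort(unique(scored[[score]]))
  n <- vapply(vals, function(v) sum(scored[[score]] == v), integer(1))
  events <- vapply(vals, function(v)
    sum(scored[[outcome]][scored[[score]] == v] == 1), integer(1))
  data.frame(score = vals, n = n, events = events,
             rate = round(100 * events / n, 1))
}

#' Score-by-outcome contingency table
#'
#' @inheritParams stratified_rates
#' @return Integer matrix, score values as rows and outcome states
#'   (`no_event`, `event`) as columns.
#' @export
outcome_contingency <- function(scored, score, outcome) {
  r <- stratified_rates(scored, score, outcome)
  m <- cbind(no_event = r$n - r$events, event = r$events)
  rownames(m) <- r$score
  m
}

#' Pearson chi-square test of independence
#'
#' Chi-square test on an r x c count table without Yates continuity
#' correction, the convention in multi-level score-by-outcome tables. Rows
#' or columns whose margin is zero are dropped with a warning before
#' testing. Cells with expected counts below 5 are reported (`n_expected_lt5`)
#' but do not switch the test to an exact alternative.
#'
#' @param counts Nonnegative integer matrix of observed counts.
#' @return Object of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `expected`, `n_expected_lt5`.
#' @examples
#' chisq_independence(matrix(c(10, 10, 10, 10), 2))  # statistic 0, p = 1
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts))
    stop("chisq_independence: counts must be nonnegative and complete",
         call. = FALSE)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping ", sum(rs == 0), " zero-margin row(s) and ",
            sum(cs == 0), " zero-margin column(s)", call. = FALSE)
    counts <- counts[rs > 0, cs > 0, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("chisq_independence: need at least a 2x2 table with nonzero margins",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    expected = ht$expected,
    n_expected_lt5 = sum(ht$expected < 5)
  ), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$n_expected_lt5 > 0)
    cat("  note:", x$n_expected_lt5, "cell(s) with expected count < 5\n")
  invisible(x)
}
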