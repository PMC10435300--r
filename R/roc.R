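# Empirical ROC analysis for integer-valued (heavily tied) scores.
# AUC uses the midrank (tie = half credit) convention throughout, which is
# what makes printed AUCs reproducible from grouped ordinal data.

check_scored <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must not contain NA", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("ROC inference requires at least one event and one non-event",
         call. = FALSE)
  invisible(TRUE)
}

# DeLong placement values. v10: one per event, P(event outranks a random
# non-event, ties half); v01: one per non-event. Computed via midranks,
# O(n log n) rather than the O(mn) pairwise sum.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n, auc = mean(v10))
}

#' Midrank AUC with DeLong variance and confidence interval
#'
#' Area under the empirical ROC curve with ties credited half:
#' the probability that a randomly chosen event scores above a randomly
#' chosen non-event, plus half the probability of a tie. Variance follows
#' DeLong's nonparametric estimator from placement values; the confidence
#' interval is a normal (Wald) interval on the AUC scale, clipped to
#' \[0, 1\]. Endpoints can therefore differ in the third decimal from
#' implementations using logit or other transformed intervals.
#'
#' @param scores Numeric vector of scores (typically small integers).
#' @param labels Binary outcome vector (1 = event), aligned with `scores`.
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return An object of class `auc_estimate`: list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `conf_level`, `n_events`, `n_nonevents`.
#' @examples
#' auc_midrank(c(0, 1, 2, 3), c(0, 0, 1, 1))  # perfect separation, AUC 1
#' @export
auc_midrank <- function(scores, labels, conf_level = 0.95) {
  check_scored(scores, labels)
  pl <- delong_placements(scores, labels)
  s10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    auc = pl$auc,
    variance = v,
    ci_low = max(0, pl$auc - z * sqrt(v)),
    ci_high = min(1, pl$auc + z * sqrt(v)),
    conf_level = conf_level,
    n_events = pl$m,
    n_nonevents = pl$n
  ), class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%% CI %.3f-%.3f), %d events / %d non-events\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$n_events, x$n_nonevents))
  invisible(x)
}

#' Empirical ROC curve points
#'
#' One point per distinct observed score cutoff (predict event iff score
#' >= cutoff), preceded by the trivial (FPR, TPR) = (0, 0) point at an
#' unattainable cutoff. The lowest cutoff always yields (1, 1). The
#' trapezoidal area under the returned points equals [auc_midrank()].
#'
#' @inheritParams auc_midrank
#' @return Data frame with columns `cutoff`, `fpr`, `tpr`, ordered by
#'   decreasing cutoff (increasing FPR).
#' @export
roc_curve <- function(scores, labels) {
  check_scored(scores, labels)
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    cutoff = cutoffs,
    fpr = vapply(cutoffs, function(cc) mean(y >= cc), numeric(1)),
    tpr = vapply(cutoffs, function(cc) mean(x >= cc), numeric(1))
  )
}

#' Operating point of a score cutoff
#'
#' Classifies score >= `cutoff` as a predicted event and fills the 2x2
#' table and its derived metrics. Sensitivity, specificity, PPV and NPV are
#' stored as unrounded percentages; printing rounds to one decimal place. A
#' metric whose denominator is zero (e.g. PPV when nothing is called
#' positive) is `NaN`.
#'
#' @inheritParams auc_midrank
#' @param cutoff Score threshold; a cutoff outside the observed score range
#'   triggers a warning but is still computed.
#' @return An object of class `operating_point`: `cutoff`, counts `tp`,
#'   `fp`, `tn`, `fn`, and percentages `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
operating_point <- function(scores, labels, cutoff) {
  check_scored(scores, labels)
  if (cutoff < min(scores) || cutoff > max(scores))
    warning("cutoff ", cutoff, " is outside the observed score range [",
            min(scores), ", ", max(scores), "]", call. = FALSE)
  pos <- scores >= cutoff
  tp <- sum(pos & labels == 1)
  fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1)
  tn <- sum(!pos & labels == 0)
  structure(list(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn)
  ), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Cutoff >=%g: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%% (TP %d, FP %d, TN %d, FN %d)\n",
    x$cutoff, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The observed score cutoff maximising Youden's J = sensitivity +
#' specificity - 1 (on the proportion scale). Ties are broken toward the
#' higher cutoff, favouring specificity.
#'
#' @inheritParams auc_midrank
#' @return List with `cutoff` and `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  check_scored(scores, labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(cc) {
    op <- suppressWarnings(operating_point(scores, labels, cc))
    (op$sensitivity + op$specificity) / 100 - 1
  }, numeric(1))
  best <- max(which(j >= max(j) - 1e-12))  # ties -> higher cutoff
  list(cutoff = cand[best], j = j[best])
}

#' DeLong paired comparison of two AUCs
#'
#' Tests whether two scores measured on the same patients discriminate an
#' outcome equally well, using the covariance of their DeLong placement
#' values. The z statistic is the AUC difference (a minus b) over its
#' paired standard error; the p-value is two-sided from the normal
#' approximation. Identical score vectors give z = 0, p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors for the same patients.
#' @param labels Binary outcome vector (1 = event) aligned with both.
#' @return An object of class `delong_comparison`: `auc_a`, `auc_b`,
#'   `z_statistic`, `p_value`, `variance_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("scores_a and scores_b must have equal length", call. = FALSE)
  check_scored(scores_a, labels)
  check_scored(scores_b, labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  if (anyNA(s10)) s10[] <- 0  # single event/non-event: no estimable variance
  if (anyNA(s01)) s01[] <- 0
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  z <- if (var_diff <= 0) {
    if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  structure(list(
    auc_a = pa$auc, auc_b = pb$auc,
    z_statistic = z,
    p_value = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)),
    variance_diff = var_diff
  ), class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z_statistic, x$p_value))
  invisible(x)
}
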