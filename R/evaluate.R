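# Evaluation reports: AUC blocks, operating points at every cutoff,
# stratified rates and chi-square association, for each (score, outcome)
# pair, plus paired DeLong comparisons when patient-level joint scores are
# available.

op_row <- function(op) {
  data.frame(cutoff = op$cutoff, tp = op$tp, fp = op$fp, tn = op$tn,
             fn = op$fn, sensitivity = op$sensitivity,
             specificity = op$specificity, ppv = op$ppv, npv = op$npv)
}

eval_block <- function(scores, labels, score_name, outcome_name,
                       cutoffs = "auto", conf_level = 0.95) {
  est <- auc_midrank(scores, labels, conf_level)
  if (identical(cutoffs, "auto"))
    cutoffs <- setdiff(sort(unique(scores)), min(scores))
  ops <- do.call(rbind, lapply(cutoffs, function(cc)
    op_row(suppressWarnings(operating_point(scores, labels, cc)))))
  yd <- youden_cutoff(scores, labels)
  ops$youden_optimal <- ops$cutoff == yd$cutoff
  scored <- data.frame(score = scores, outcome = labels)
  rates <- stratified_rates(scored, "score", "outcome")
  chi <- chisq_independence(outcome_contingency(scored, "score", "outcome"))
  list(score = score_name, outcome = outcome_name,
       auc = unclass(est)[c("auc", "variance", "ci_low", "ci_high",
                            "conf_level", "n_events", "n_nonevents")],
       operating_points = ops,
       youden = yd,
       rates = rates,
       chisq = unclass(chi)[c("statistic", "df", "p_value", "n_expected_lt5")])
}

#' Evaluate scores in a patient-level scored cohort
#'
#' For every (score, outcome) pair, computes the midrank AUC with DeLong
#' confidence interval, operating-point metrics at each requested cutoff
#' (flagging the Youden optimum), score-stratified outcome rates and the
#' Pearson chi-square association test. When exactly two score columns are
#' evaluated, paired DeLong comparisons of their AUCs are added per
#' outcome. Outcomes with no events (or no non-events) are skipped with a
#' warning.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param scores Character vector of score column names.
#' @param outcomes Character vector of binary outcome column names present
#'   in `scored`.
#' @param cutoffs `"auto"` (every observed cutoff above the minimum score)
#'   or an integer vector of cutoffs.
#' @param conf_level Confidence level for AUC intervals.
#' @return Object of class `score_evaluation`: list with `blocks` (one per
#'   score x outcome), `comparisons` (paired DeLong tests, possibly empty)
#'   and `skipped` (degenerate outcomes).
#' @export
evaluate_cohort <- function(scored,
                            scores = intersect(c("smart", "qsofa"), names(scored)),
                            outcomes = intersect(c("died_7d", "died_30d", "icu_admit"),
                                                 names(scored)),
                            cutoffs = "auto", conf_level = 0.95) {
  scored <- as.data.frame(scored, stringsAsFactors = FALSE)
  if (!length(scores))
    stop("evaluate_cohort: no score columns to evaluate", call. = FALSE)
  for (col in c(scores, outcomes))
    if (!col %in% names(scored))
      stop("evaluate_cohort: no column named '", col, "'", call. = FALSE)

  skipped <- character()
  usable <- character()
  for (oc in outcomes) {
    lab <- scored[[oc]]
    if (sum(lab == 1) < 1 || sum(lab == 0) < 1) {
      warning("outcome '", oc, "' is degenerate (no events or no non-events); ",
              "block omitted", call. = FALSE)
      skipped <- c(skipped, oc)
    } else usable <- c(usable, oc)
  }

  blocks <- list()
  for (sc in scores)
    for (oc in usable)
      blocks[[paste(sc, oc, sep = ".")]] <-
        eval_block(scored[[sc]], scored[[oc]], sc, oc, cutoffs, conf_level)

  comparisons <- list()
  if (length(scores) == 2)
    for (oc in usable) {
      cmp <- delong_test(scored[[scores[1]]], scored[[scores[2]]], scored[[oc]])
      comparisons[[oc]] <- c(list(score_a = scores[1], score_b = scores[2],
                                  outcome = oc), unclass(cmp))
    }

  structure(list(blocks = blocks, comparisons = comparisons,
                 skipped = skipped),
            class = "score_evaluation")
}

#' Evaluate the bundled reference cohort
#'
#' Runs the full evaluation on the grouped reference reconstruction for
#' both scores and all three outcomes. The grouped form fixes each score's
#' marginal (score, outcome) distribution but not the joint distribution of
#' the two scores across patients, so no paired DeLong comparison is
#' possible here; `comparisons` is empty with an explanatory note.
#'
#' @inheritParams evaluate_cohort
#' @return A `score_evaluation`.
#' @export
evaluate_reference <- function(cutoffs = "auto", conf_level = 0.95) {
  blocks <- list()
  for (sc in c("smart", "qsofa")) {
    tb <- reference_cohort(sc)
    for (oc in c("died_7d", "died_30d", "icu_admit")) {
      so <- expand_grouped(tb, oc)
      blocks[[paste(sc, oc, sep = ".")]] <-
        eval_block(so$score, so$label, sc, oc, cutoffs, conf_level)
    }
  }
  structure(list(blocks = blocks, comparisons = list(),
                 skipped = character(),
                 note = paste("grouped reconstruction: joint score",
                              "distribution unknown, paired AUC comparison",
                              "not computable")),
            class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat("Score evaluation:", length(x$blocks), "block(s)\n")
  for (b in x$blocks)
    cat(sprintf("  %-6s vs %-10s AUC %.3f (%.3f-%.3f), Youden cutoff >=%g, chi-square p = %.3g\n",
                b$score, b$outcome, b$auc$auc, b$auc$ci_low, b$auc$ci_high,
                b$youden$cutoff, b$chisq$p_value))
  for (cmp in x$comparisons)
    cat(sprintf("  %s: %s %.3f vs %s %.3f, DeLong p = %.3g\n", cmp$outcome,
                cmp$score_a, cmp$auc_a, cmp$score_b, cmp$auc_b, cmp$p_value))
  if (length(x$skipped))
    cat("  skipped degenerate outcome(s):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten an evaluation's operating points or rates to data frames
#'
#' @param evaluation A `score_evaluation`.
#' @return A data frame with one row per (score, outcome, cutoff) or per
#'   (score, outcome, score value).
#' @export
operating_points_table <- function(evaluation) {
  do.call(rbind, lapply(evaluation$blocks, function(b)
    cbind(score = b$score, outcome = b$outcome, b$operating_points,
          row.names = NULL)))
}

#' @rdname operating_points_table
#' @export
rates_table <- function(evaluation) {
  do.call(rbind, lapply(evaluation$blocks, function(b)
    data.frame(score = b$score, outcome = b$outcome,
               score_value = b$rates$score, n = b$rates$n,
               events = b$rates$events, rate = b$rates$rate,
               row.names = NULL)))
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (the machine-readable source of truth),
#' `report_operating_points.csv` and `report_rates.csv` under `dir`.
#' Percentages in the CSV views are rounded to one decimal place; the JSON
#' keeps full precision.
#'
#' @param evaluation A `score_evaluation`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the path of the JSON report.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(evaluation), json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  ops <- operating_points_table(evaluation)
  for (col in c("sensitivity", "specificity", "ppv", "npv"))
    ops[[col]] <- round(ops[[col]], 1)
  utils::write.csv(ops, file.path(dir, "report_operating_points.csv"),
                   row.names = FALSE)
  utils::write.csv(rates_table(evaluation), file.path(dir, "report_rates.csv"),
                   row.names = FALSE)
  invisible(json_path)
}

#' Compare an evaluation against the bundled expected performance table
#'
#' The package ships the published headline performance of both scores on
#' the reference cohort (AUC per outcome, and
#' sensitivity/specificity/PPV/NPV at the published cutoffs) in
#' `inst/extdata/reference_performance.csv`. This helper diffs a computed
#' evaluation against that table: AUCs at 3 decimal places,
#' operating-point percentages at 1.
#'
#' @param evaluation A `score_evaluation` covering both scores and all
#'   three outcomes (e.g. from [evaluate_reference()]).
#' @return Data frame with columns `score`, `outcome`, `quantity`,
#'   `expected`, `computed`, `matched`.
#' @export
check_reference_reproduction <- function(evaluation) {
  exp_path <- system.file("extdata", "reference_performance.csv",
                          package = "smartriage", mustWork = TRUE)
  expected <- utils::read.csv(exp_path, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    b <- evaluation$blocks[[paste(e$score, e$outcome, sep = ".")]]
    if (is.null(b))
      stop("check_reference_reproduction: evaluation lacks block ",
           e$score, " x ", e$outcome, call. = FALSE)
    op <- b$operating_points[b$operating_points$cutoff == e$cutoff, ]
    comp <- c(auc = round(b$auc$auc, 3),
              sensitivity = round(op$sensitivity, 1),
              specificity = round(op$specificity, 1),
              ppv = round(op$ppv, 1),
              npv = round(op$npv, 1))
    want <- c(auc = e$auc, sensitivity = e$sensitivity,
              specificity = e$specificity, ppv = e$ppv, npv = e$npv)
    rows[[i]] <- data.frame(
      score = e$score, outcome = e$outcome, quantity = names(comp),
      expected = unname(want), computed = unname(comp),
      matched = abs(unname(comp) - unname(want)) < 1e-9,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
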