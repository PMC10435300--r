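test_that("midrank AUC handles separation, ties and degenerate labels", {
  expect_equal(auc_midrank(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_midrank(c(1, 1), c(1, 0))$auc, 0.5)
  expect_error(auc_midrank(c(1, 2), c(1, 1)), "at least one event")
  expect_error(auc_midrank(c(1, 2), c(0, 0)), "at least one event")
  expect_error(auc_midrank(c(1, 2), c(0, NA)), "NA")
})

test_that("midrank AUC equals the exhaustive pair-counting oracle", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_scored(sample(4:200, 1))
    expect_equal(auc_midrank(inst$scores, inst$labels)$auc,
                 auc_pair_oracle(inst$scores, inst$labels))
  }
})

test_that("AUC respects label complement and score translation symmetries", {
  set.seed(55)
  for (i in 1:25) {
    inst <- random_scored(sample(10:100, 1))
    a <- auc_midrank(inst$scores, inst$labels)
    expect_equal(auc_midrank(inst$scores, 1 - inst$labels)$auc, 1 - a$auc)
    shift <- sample(-5:5, 1)
    b <- auc_midrank(inst$scores + shift, inst$labels)
    expect_equal(b$auc, a$auc)
    expect_equal(b$variance, a$variance)
    op_a <- operating_point(inst$scores, inst$labels, 2)
    op_b <- suppressWarnings(
      operating_point(inst$scores + shift, inst$labels, 2 + shift))
    expect_equal(op_a$sensitivity, op_b$sensitivity)
    expect_equal(op_a$specificity, op_b$specificity)
  }
})

test_that("DeLong CI brackets the estimate and is clipped to [0, 1]", {
  set.seed(77)
  for (i in 1:20) {
    inst <- random_scored(sample(6:80, 1))
    est <- auc_midrank(inst$scores, inst$labels)
    expect_gte(est$variance, 0)
    expect_lte(est$ci_low, est$auc)
    expect_gte(est$ci_high, est$auc)
    expect_gte(est$ci_low, 0)
    expect_lte(est$ci_high, 1)
  }
  perfect <- auc_midrank(c(0, 0, 5, 5), c(0, 0, 1, 1))
  expect_equal(perfect$ci_high, 1)
})

test_that("ROC curve enumerates cutoffs and its trapezoid area is the AUC", {
  # perfect separation over two distinct scores: (0,0), (0,1), (1,1)
  rc <- roc_curve(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(rc$fpr, c(0, 0, 1))
  expect_equal(rc$tpr, c(0, 1, 1))
  # single shared score: chance diagonal endpoints only
  rc1 <- roc_curve(c(2, 2), c(0, 1))
  expect_equal(nrow(rc1), 2L)
  expect_equal(rc1$fpr, c(0, 1))

  trapezoid <- function(rc) sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  set.seed(9)
  for (i in 1:30) {
    inst <- random_scored(sample(5:120, 1))
    rc <- roc_curve(inst$scores, inst$labels)
    expect_equal(nrow(rc), length(unique(inst$scores)) + 1L)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_lt(abs(trapezoid(rc) - auc_midrank(inst$scores, inst$labels)$auc),
              1e-12)
  }
})

test_that("operating points fill a consistent 2x2 table at any cutoff", {
  inst <- list(scores = c(0, 1, 1, 2, 3, 3), labels = c(0, 0, 1, 0, 1, 1))
  op <- operating_point(inst$scores, inst$labels, 2)
  expect_identical(op$tp + op$fn, 3L)
  expect_identical(op$tn + op$fp, 3L)
  expect_equal(op$sensitivity, 100 * op$tp / (op$tp + op$fn))
  expect_equal(op$ppv, 100 * op$tp / (op$tp + op$fp))
  # cutoff at/below the minimum: everything called positive
  op0 <- operating_point(inst$scores, inst$labels, 0)
  expect_equal(op0$sensitivity, 100)
  expect_equal(op0$specificity, 0)
  expect_true(is.nan(op0$npv))
  expect_warning(operating_point(inst$scores, inst$labels, 99), "outside")
})

test_that("sensitivity falls and specificity rises as the cutoff increases", {
  set.seed(21)
  for (i in 1:20) {
    inst <- random_scored(sample(10:100, 1))
    cuts <- sort(unique(inst$scores))
    ops <- lapply(cuts, function(cc)
      suppressWarnings(operating_point(inst$scores, inst$labels, cc)))
    sens <- vapply(ops, `[[`, numeric(1), "sensitivity")
    spec <- vapply(ops, `[[`, numeric(1), "specificity")
    expect_true(all(diff(sens) <= 1e-12))
    expect_true(all(diff(spec) >= -1e-12))
    # PPV consistency with Bayes' rule at prevalence from the table
    op <- ops[[ceiling(length(ops) / 2)]]
    prev <- (op$tp + op$fn) / (op$tp + op$fn + op$tn + op$fp)
    se <- op$sensitivity / 100; sp <- op$specificity / 100
    bayes_ppv <- 100 * se * prev / (se * prev + (1 - sp) * (1 - prev))
    if (!is.nan(op$ppv)) expect_equal(op$ppv, bayes_ppv)
  }
})

test_that("Youden cutoff maximises J and breaks ties upward", {
  expect_equal(youden_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1)),
               list(cutoff = 2, j = 1))
  expect_equal(youden_cutoff(c(1, 1, 1), c(0, 1, 1))$j, 0)
  # events at {1,3}, non-events at {0,2}: J = 0.5 at cutoffs 1, 2 and 3
  tie <- youden_cutoff(c(1, 3, 0, 2), c(1, 1, 0, 0))
  expect_equal(tie$cutoff, 3)
  expect_equal(tie$j, 0.5)
})

test_that("paired DeLong test is null on identical scores and antisymmetric", {
  set.seed(31)
  inst <- random_scored(40)
  same <- delong_test(inst$scores, inst$scores, inst$labels)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 1)

  other <- sample(0:5, 40, replace = TRUE)
  ab <- delong_test(inst$scores, other, inst$labels)
  ba <- delong_test(other, inst$scores, inst$labels)
  expect_equal(ab$z_statistic, -ba$z_statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("paired DeLong test recognises a perfect classifier on small n", {
  labels <- c(0, 1, 0, 1, 1, 0, 0, 1)
  set.seed(8)
  noisy <- sample(0:3, 8, replace = TRUE)
  cmp <- delong_test(noisy, labels, labels)
  expect_equal(cmp$auc_b, 1)
  expect_equal(cmp$auc_b, auc_pair_oracle(labels, labels))
  expect_equal(cmp$auc_a, auc_pair_oracle(noisy, labels))
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("DeLong variance shrinks roughly as 1/k under sample duplication", {
  set.seed(13)
  inst <- random_scored(60)
  v1 <- auc_midrank(inst$scores, inst$labels)$variance
  k <- 4
  vk <- auc_midrank(rep(inst$scores, k), rep(inst$labels, k))$variance
  expect_equal(v1 / vk, k, tolerance = 0.1)
})

test_that("AUC and paired test agree with an independent ROC implementation", {
  set.seed(19)
  for (i in 1:5) {
    inst <- random_scored(80)
    other <- pmin(5, pmax(0, inst$scores + sample(-1:1, 80, replace = TRUE)))
    ref <- pROC::roc(inst$labels, inst$scores, quiet = TRUE, direction = "<")
    expect_equal(auc_midrank(inst$scores, inst$labels)$auc, as.numeric(ref$auc))
    ci <- pROC::ci.auc(ref, method = "delong")
    est <- auc_midrank(inst$scores, inst$labels)
    expect_equal(est$ci_low, max(0, as.numeric(ci)[1]), tolerance = 1e-8)
    expect_equal(est$ci_high, min(1, as.numeric(ci)[3]), tolerance = 1e-8)
    ref2 <- pROC::roc(inst$labels, other, quiet = TRUE, direction = "<")
    ours <- delong_test(inst$scores, other, inst$labels)
    theirs <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
    expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-8)
  }
})
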