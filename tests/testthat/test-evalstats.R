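test_that("diagnostic metrics reproduce hand values and flag undefined ratios", {
  m <- diagnostic_metrics(confusion_matrix(tp = 11, fp = 41, tn = 155, fn = 1))
  expect_equal(round(m$accuracy, 2), 79.81)
  expect_equal(round(m$sensitivity, 2), 91.67)
  expect_equal(round(m$specificity, 2), 79.08)
  expect_equal(round(m$ppv, 2), 21.15)
  expect_equal(round(m$npv, 2), 99.36)

  m <- diagnostic_metrics(confusion_matrix(tp = 7, fp = 29, tn = 167, fn = 5))
  expect_equal(round(c(m$ppv, m$npv, m$accuracy), 2), c(19.44, 97.09, 83.65))

  m <- diagnostic_metrics(confusion_matrix(tp = 5, fp = 0, tn = 7, fn = 0))
  expect_equal(unlist(m), c(accuracy = 100, sensitivity = 100,
                            specificity = 100, ppv = 100, npv = 100))

  expect_warning(m <- diagnostic_metrics(confusion_matrix(0, 0, 10, 5)),
                 "positive predictive value undefined")
  expect_true(is.na(m$ppv))
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("confusion reconstruction inverts printed sensitivity/specificity rows", {
  cm <- reconstruct_confusion(91.67, 79.08, 12, 196)
  expect_equal(unlist(cm), c(tp = 11L, fp = 41L, tn = 155L, fn = 1L))
  cm <- reconstruct_confusion(100, 100, 5, 5)
  expect_equal(unlist(cm), c(tp = 5L, fp = 0L, tn = 5L, fn = 0L))
  cm <- reconstruct_confusion(50.00, 82.65, 12, 196)
  expect_equal(cm$tp, 6L)
  expect_equal(cm$tn, 162L)
})

test_that("trapezoidal AUC equals the concordance-probability pair loop", {
  set.seed(1)
  labs <- rep(c("death", "survivor"), c(40, 160))
  sc <- rnorm(200)
  r <- roc_auc(sc, labs)
  expect_equal(r$auc, bf_auc(sc, labs), tolerance = 1e-14)
  # heavy ties: scores on a coarse grid
  sc2 <- sample(seq(0, 1, by = 0.1), 200, replace = TRUE)
  expect_equal(roc_auc(sc2, labs)$auc, bf_auc(sc2, labs), tolerance = 1e-14)
  # perfect separation
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)),
                       rep(c("death", "survivor"), each = 5))$auc, 1)
  # operating points are monotone and anchored at (0, 0)
  expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  # invariance under strictly monotone score transforms
  expect_equal(roc_auc(plogis(3 * sc - 1), labs)$auc, r$auc, tolerance = 1e-14)
  expect_error(roc_auc(sc, rep("survivor", 200)), "both classes")
})

test_that("DeLong comparison separates informative from useless scores", {
  set.seed(2)
  labs <- rep(c("death", "survivor"), c(60, 140))
  good <- ifelse(labs == "death", 1, 0) + rnorm(200, sd = 0.5)
  junk <- rnorm(200)
  cmp <- compare_rocs(good, junk, labs)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$auc_a, cmp$auc_b)

  same <- compare_rocs(junk, junk, labs)
  expect_equal(same$p_value, 1)
  expect_equal(same$delta, 0)
})

test_that("threshold comparators use strict lower cutoffs", {
  thr <- comparator_thresholds()
  expect_equal(as.character(threshold_classifier(69.9, thr[["sdnn"]])), "death")
  expect_equal(as.character(threshold_classifier(70.0, thr[["sdnn"]])), "survivor")
  expect_equal(as.character(threshold_classifier(4.5, thr[["dc"]])), "survivor")
  expect_equal(as.character(threshold_classifier(4.49, thr[["dc"]])), "death")
  expect_equal(as.character(threshold_classifier(0.34, thr[["lvef"]])), "death")
})

test_that("LVEF subgroup filter retains strictly preserved ventricular function", {
  # cohort shaped like the reference baseline table: 9/196 survivors and
  # 3/12 deaths below the 0.35 cutoff
  lvef <- c(rep(0.55, 187), rep(0.30, 9), rep(0.50, 9), rep(0.25, 3))
  outcome <- rep(c("survivor", "death"), c(196, 12))
  coh <- data.frame(lvef = lvef, outcome = factor(outcome,
                    levels = c("survivor", "death")))
  sub <- subgroup_filter(coh)
  cnt <- attr(sub, "class_counts")
  expect_equal(unname(cnt["survivor"]), 187)
  expect_equal(unname(cnt["death"]), 9)

  # boundary: exactly 0.35 is excluded from the > 0.35 subgroup
  coh2 <- data.frame(lvef = c(0.35, 0.351), outcome = factor(
    c("survivor", "survivor"), levels = c("survivor", "death")))
  expect_equal(nrow(subgroup_filter(coh2)), 1)
  # no patient below the bound: identity filter
  coh3 <- data.frame(lvef = rep(0.6, 5), outcome = factor(
    rep("survivor", 5), levels = c("survivor", "death")))
  expect_equal(nrow(subgroup_filter(coh3)), 5)
})
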