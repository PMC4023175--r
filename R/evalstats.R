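#' Confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative integer counts (true/false positives and
#'   negatives; "positive" = cardiac death).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion-matrix counts must be non-negative integers")
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_matrix")
}

#' Confusion matrix from predicted and true labels
#'
#' @param truth,predicted Factors/characters with values `survivor`/`death`;
#'   death is the positive class.
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  confusion_matrix(tp = sum(truth == "death" & predicted == "death"),
                   fp = sum(truth == "survivor" & predicted == "death"),
                   tn = sum(truth == "survivor" & predicted == "survivor"),
                   fn = sum(truth == "death" & predicted == "survivor"))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, positive
#' predictive value `100*tp/(tp+fp)`, negative predictive value
#' `100*tn/(tn+fn)` and accuracy `100*(tp+tn)/n`, all in percent. A metric
#' whose denominator is zero is undefined and returned as `NA` with a
#' warning.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row data frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent).
#' @export
#' @examples
#' diagnostic_metrics(confusion_matrix(tp = 11, fp = 41, tn = 155, fn = 1))
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  with(cm, data.frame(
    accuracy    = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    ppv         = ratio(tp, tp + fp, "positive predictive value"),
    npv         = ratio(tn, tn + fn, "negative predictive value")
  ))
}

# nearest integer, halves away from zero (commercial rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reconstruct an integer confusion matrix from printed summary statistics
#'
#' Given published sensitivity and specificity (percent) and the class
#' sizes, recovers the integer confusion matrix: `tp` is the nearest integer
#' (halves away from zero) to `sens * n_pos / 100`, `tn` likewise from the
#' specificity, and `fn`, `fp` follow by complement. Feeding the result back
#' through [diagnostic_metrics()] checks a published table row for internal
#' consistency.
#'
#' @param sensitivity,specificity Percentages as printed.
#' @param n_pos,n_neg Class sizes (deaths, survivors).
#' @return A [confusion_matrix()].
#' @export
#' @examples
#' reconstruct_confusion(91.67, 79.08, 12, 196)   # tp 11, fn 1, tn 155, fp 41
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  tp <- round_half_away(sensitivity * n_pos / 100)
  tn <- round_half_away(specificity * n_neg / 100)
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' ROC curve and AUC
#'
#' Sweeps the threshold over all distinct score values (ties move operating
#' points simultaneously) and integrates sensitivity against false-positive
#' rate by the trapezoidal rule. The resulting AUC equals the Mann-Whitney
#' concordance probability with half-credit for tied scores.
#'
#' @param scores Numeric risk scores (larger = more death-like).
#' @param labels Outcomes (`survivor`/`death`, death positive).
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, including the (0,0) endpoint) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("survivor", "death")))
  pos <- labels == "death"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("ROC requires both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yp <- pos[o]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tps <- cumsum(yp)[last_of_tie]
  fps <- cumsum(!yp)[last_of_tie]
  pts <- data.frame(threshold = c(Inf, s[last_of_tie]),
                    fpr = c(0, fps / N), tpr = c(0, tps / P))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = unname(auc)), class = "roc_curve")
}

#' Compare two correlated ROC curves
#'
#' DeLong's nonparametric test for paired AUCs: both score vectors are
#' evaluated on the same patients, so the covariance of the two empirical
#' AUCs is estimated from the paired placement values. Two identical score
#' vectors have AUC difference exactly zero and p-value 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared outcomes (`survivor`/`death`).
#' @return List with `auc_a`, `auc_b`, `delta` and two-sided `p_value`.
#' @export
compare_rocs <- function(scores_a, scores_b, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = auc_a, auc_b = auc_b, delta = 0, p_value = 1))
  resp <- factor(labels, levels = c("survivor", "death"))
  ra <- pROC::roc(resp, scores_a, levels = c("survivor", "death"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(resp, scores_b, levels = c("survivor", "death"),
                  direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
       p_value = as.numeric(tst$p.value))
}

#' Single-index threshold classifier
#'
#' The conventional comparators dichotomize one feature at a prespecified
#' cutoff: values strictly below the cutoff are abnormal and predict cardiac
#' death (SDNN < 70 ms, DC < 4.5 ms, LVEF < 0.35).
#'
#' @param values Numeric feature values.
#' @param cutoff Abnormality cutoff.
#' @param direction `"below"` (default): abnormal iff `value < cutoff`.
#' @return Factor with levels `survivor`, `death`.
#' @export
#' @examples
#' threshold_classifier(c(69.9, 70), comparator_thresholds()["sdnn"])
threshold_classifier <- function(values, cutoff, direction = c("below", "above")) {
  direction <- match.arg(direction)
  abn <- if (direction == "below") values < cutoff else values > cutoff
  factor(ifelse(abn, "death", "survivor"), levels = c("survivor", "death"))
}

#' Restrict a cohort to preserved ventricular function
#'
#' Retains patients with LVEF strictly above the cutoff (default 0.35) —
#' the subgroup in which LVEF itself flags nobody as high-risk, where HRV
#' methods have to do all the work.
#'
#' @param cohort Feature table with an `lvef` column.
#' @param lvef_min Exclusive lower bound.
#' @return The filtered cohort, with per-class counts in attribute
#'   `class_counts`.
#' @export
subgroup_filter <- function(cohort, lvef_min = 0.35) {
  stopifnot(is.data.frame(cohort), "lvef" %in% names(cohort))
  keep <- cohort$lvef > lvef_min
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if ("outcome" %in% names(out))
    attr(out, "class_counts") <- table(out$outcome)
  out
}
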