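# Binary-classification performance metrics: precision, recall, F1, the
# rank-statistic AUC, and the Matthews correlation coefficient.

#' Confusion counts
#'
#' @param predicted predicted binary labels (0/1).
#' @param truth true binary labels (0/1).
#' @return named integer vector `TP`, `TN`, `FP`, `FN` (sums to `n`).
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as.integer(predicted); y <- as.integer(truth)
  stopifnot(length(p) == length(y), all(p %in% 0:1), all(y %in% 0:1))
  c(TP = sum(p == 1 & y == 1), TN = sum(p == 0 & y == 0),
    FP = sum(p == 1 & y == 0), FN = sum(p == 0 & y == 1))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from ranks:
#' `AUC = (sum of positive ranks - M(M+1)/2) / (M N)` with `M` positives and
#' `N` negatives; tied scores receive average ranks, so ties between a
#' positive and a negative contribute 1/2, exactly as in brute-force
#' pair counting.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
rank_auc <- function(scores, labels) {
  y <- as.integer(labels)
  M <- sum(y == 1); N <- sum(y == 0)
  if (M == 0 || N == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - M * (M + 1) / 2) / (M * N)
}

#' Classification metrics report
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (their harmonic mean),
#' rank AUC (when scores are given) and MCC. Zero denominators are guarded:
#' precision/recall/F1 fall back to 0 when undefined, and MCC returns 0 when
#' any factor of its denominator is 0 (the standard convention).
#'
#' @param predicted predicted binary labels.
#' @param truth true binary labels.
#' @param scores optional numeric scores for the AUC.
#' @return object of class `ctpdn_metrics`: list with `counts`, `precision`,
#'   `recall`, `f1`, `auc`, `mcc`, `M`, `N`.
#' @export
cti_metrics <- function(predicted, truth, scores = NULL) {
  cc <- confusion_counts(predicted, truth)
  TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom > 0) (TP * TN - FP * FN) / denom else 0
  auc <- if (!is.null(scores)) rank_auc(scores, truth) else NA_real_
  structure(list(counts = cc, precision = precision, recall = recall,
                 f1 = f1, auc = auc, mcc = mcc,
                 M = TP + FN, N = TN + FP),
            class = "ctpdn_metrics")
}

#' @export
print.ctpdn_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  AUC %s  MCC %.4f\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$mcc))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d  (M=%d positives, N=%d negatives)\n",
              x$counts[["TP"]], x$counts[["TN"]], x$counts[["FP"]],
              x$counts[["FN"]], x$M, x$N))
  invisible(x)
}

#' Decision-stump baseline classifier
#'
#' A single depth-one tree behind the same fit/predict interface, used as
#' the comparison baseline for the boosted ensemble.
#'
#' @inheritParams fit_adaboost
#' @return a `ctpdn_adaboost` object with a single learner.
#' @export
fit_stump_baseline <- function(table, labels = NULL, seed = 1L) {
  fit_adaboost(table, labels, max_splits = 1, n_learners = 1,
               learning_rate = 1, seed = seed)
}
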