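# Confusion-matrix metrics and ROC/AUC.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Factors or label vectors; `levels` fixes the class order
#'   (default: anatomical region order).
#' @param levels Class levels.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, levels = names(REGIONS)) {
  t <- factor(truth, levels = levels)
  p <- factor(pred, levels = levels)
  unclass(table(truth = t, predicted = p))
}

#' Per-class metrics from a confusion matrix
#'
#' Dissects the multiclass confusion matrix into one-vs-rest binary problems
#' and computes, per class, recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2*precision*recall/(precision+recall) and accuracy =
#' (TP+TN)/(TP+FP+TN+FN). A metric whose denominator is zero is reported as 0
#' and flagged in the `degenerate` column. The overall (macro) accuracy is
#' trace/total.
#'
#' @param cm Square counts matrix (rows = true, columns = predicted).
#' @return A `metrics_report`: list with `per_class` data frame (`class`,
#'   `TP`, `FP`, `FN`, `TN`, `recall`, `precision`, `f1`, `accuracy`,
#'   `degenerate`) and scalar `overall_accuracy`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  safe <- function(num, den) if (den > 0) num / den else 0
  rows <- lapply(seq_len(nrow(cm)), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    rec <- safe(TP, TP + FN)
    prec <- safe(TP, TP + FP)
    f1 <- safe(2 * prec * rec, prec + rec)
    acc <- safe(TP + TN, total)
    data.frame(class = classes[k], TP = TP, FP = FP, FN = FN, TN = TN,
               recall = rec, precision = prec, f1 = f1, accuracy = acc,
               degenerate = (TP + FN == 0) || (TP + FP == 0) ||
                 (prec + rec == 0))
  })
  structure(list(per_class = do.call(rbind, rows),
                 overall_accuracy = if (total > 0) sum(diag(cm)) / total else 0),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Overall accuracy:", sprintf("%.3f", x$overall_accuracy), "\n")
  df <- x$per_class
  df[, c("recall", "precision", "f1", "accuracy")] <-
    round(df[, c("recall", "precision", "f1", "accuracy")], 3)
  print(df[, c("class", "recall", "precision", "f1", "accuracy")],
        row.names = FALSE)
  invisible(x)
}

# Midrank (Mann-Whitney) AUC of scores for a binary indicator.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUC per class
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie handling, one class
#' against the rest. A class with no positive or no negative sample gets
#' `NA` with a warning.
#'
#' @param probs Numeric matrix of class probabilities (columns named by
#'   class).
#' @param labels True labels.
#' @return Named numeric vector of per-class AUCs.
#' @export
roc_auc <- function(probs, labels) {
  stopifnot(is.matrix(probs), !is.null(colnames(probs)),
            nrow(probs) == length(labels))
  out <- vapply(colnames(probs), function(k) {
    auc_rank(probs[, k], labels == k)
  }, 0)
  if (anyNA(out))
    warning("AUC undefined for class(es) without both positives and ",
            "negatives: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' One-vs-rest ROC curve coordinates
#'
#' @param scores Numeric scores for the positive class.
#' @param positive Logical indicator of the positive class.
#' @return Data frame of `threshold`, `fpr`, `tpr`, from (1, 1) to (0, 0).
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(positive); n0 <- sum(!positive)
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = if (n0) sum(pred & !positive) / n0 else 0,
               tpr = if (n1) sum(pred & positive) / n1 else 0)
  }))
}

#' Majority vote over per-slice predictions
#'
#' Returns the label receiving more than 50% of the votes; when no label
#' exceeds 50%, the label with the highest mean class probability wins; with
#' no probabilities, the plurality label (first in class order on ties).
#'
#' @param votes Character vector of predicted labels (one per slice).
#' @param probs Optional numeric matrix of per-slice class probabilities
#'   (columns named by class).
#' @return Single predicted label.
#' @export
majority_vote <- function(votes, probs = NULL) {
  stopifnot(length(votes) >= 1L)
  lev <- if (!is.null(probs)) colnames(probs) else unique(votes)
  cnt <- table(factor(votes, levels = lev))
  if (max(cnt) > length(votes) / 2) return(names(cnt)[which.max(cnt)])
  if (!is.null(probs)) {
    stopifnot(nrow(probs) == length(votes))
    return(colnames(probs)[which.max(colMeans(probs))])
  }
  names(cnt)[which.max(cnt)]
}
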