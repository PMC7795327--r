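# Evaluation metrics: accuracy, precision, sensitivity, F1 and the
# Matthews correlation coefficient from one-vs-all confusion counts, plus
# the binary ROC AUC as the Mann-Whitney statistic.

#' Confusion matrix from true and predicted labels
#'
#' Integer counts with rows = true class, columns = predicted class, over
#' the union of levels.
#'
#' @param truth,predicted label vectors of equal length.
#' @param levels optional class ordering.
#' @return a `table`.
#' @export
confusionMatrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) stop("empty confusion matrix")
  if (is.null(levels)) {
    levels <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  }
  table(
    truth = factor(truth, levels = levels),
    predicted = factor(predicted, levels = levels)
  )
}

#' One-vs-all binary counts for one class
#'
#' Collapses a multiclass confusion matrix to (TP, FN, FP, TN) for the
#' given positive class; the four counts always sum to the total.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param positive positive class name.
#' @return named numeric vector (TP, FN, FP, TN).
#' @export
oneVsAll <- function(cm, positive) {
  cm <- as.matrix(cm)
  if (!positive %in% rownames(cm)) stop("unknown positive class")
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Classification metrics for one positive class
#'
#' Accuracy, precision, sensitivity, F1 and Matthews correlation
#' coefficient from the one-vs-all collapse of a confusion matrix.
#' Zero-denominator conventions: precision, sensitivity and F1 are 0
#' when undefined; MCC is 0 when any marginal is zero (the value a
#' degenerate all-one-class predictor deserves).
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param positive positive class name.
#' @return named numeric vector with accuracy, precision, sensitivity,
#'   f1 and mcc.
#' @export
metricsFromConfusion <- function(cm, positive) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  b <- oneVsAll(cm, positive)
  tp <- b["TP"]
  fn <- b["FN"]
  fp <- b["FP"]
  tn <- b["TN"]
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if ((tp + fp) > 0) tp / (tp + fp) else 0
  sens <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  f1 <- if ((prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen > 0) {
    (tp * tn - fp * fn) / sqrt(mccDen)
  } else {
    0
  }
  c(
    accuracy = unname(acc), precision = unname(prec),
    sensitivity = unname(sens), f1 = unname(f1), mcc = unname(mcc)
  )
}

#' Overall multiclass accuracy
#'
#' `trace(cm) / total`: the fraction of correctly classified events.
#'
#' @param cm confusion matrix.
#' @return accuracy in \[0, 1\].
#' @export
overallAccuracy <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm)
}

#' Binary ROC AUC (Mann-Whitney statistic)
#'
#' Probability that a random positive scores above a random negative,
#' with ties credited 0.5.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or two-level labels; `positive` names the
#'   positive level for non-logical input.
#' @param positive positive class for factor/character labels.
#' @return AUC in \[0, 1\].
#' @export
aucBinary <- function(scores, labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.factor(labels)
    if (nlevels(droplevels(labels)) != 2L && is.null(positive)) {
      stop("labels must have exactly two levels")
    }
    if (is.null(positive)) positive <- levels(droplevels(labels))[2]
    pos <- labels == positive
  }
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
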