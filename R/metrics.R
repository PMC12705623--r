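# Prediction head, loss and evaluation metrics.

#' Two-class prediction head
#'
#' Layer-normalizes each representation row, applies a linear map to two
#' logits and a row-wise softmax. Rows sum to one.
#'
#' @param R N x d matrix of prescription representations.
#' @param W d x 2 weight matrix.
#' @param b Length-2 (or 1 x 2) bias.
#' @return N x 2 matrix of class probabilities (column 2 = positive).
#' @export
predict_head <- function(R, W, b = c(0, 0)) {
  R <- as.matrix(R)
  mu <- rowMeans(R)
  sdv <- sqrt(rowMeans((R - mu)^2) + 1e-5)
  Z <- ((R - mu) / sdv) %*% W
  softmax_rows(sweep(Z, 2, as.numeric(b), "+"))
}

#' Classify from two-class probabilities
#'
#' Argmax over the two columns; an exact tie is resolved to the negative
#' class (conservative tie-break). Column 2 is the positive class.
#'
#' @param y_prob N x 2 matrix (or length-2 vector) of scores.
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(y_prob) {
  m <- matrix(y_prob, ncol = 2)
  as.integer(m[, 2] > m[, 1])
}

#' Binary cross-entropy
#'
#' `-(1-y) log(1-x) - y log(x)` with `x` clamped to `[eps, 1-eps]`.
#'
#' @param y True 0/1 labels.
#' @param x Predicted probability of the positive class.
#' @param eps Clamp bound (default 1e-7).
#' @return Mean loss over the inputs (scalar, >= 0).
#' @export
bce_loss <- function(y, x, eps = 1e-7) {
  x <- pmin(pmax(x, eps), 1 - eps)
  mean(-(1 - y) * log(1 - x) - y * log(x))
}

# Rank-based AUC (Wilcoxon statistic with midranks for ties).
auc_score <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve as average precision:
# sum over descending-score thresholds of (delta recall) * precision.
aupr_score <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  if (n1 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # evaluate only at the last index of each tied score block
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate binary classification scores
#'
#' AUC and AUPR from rank-based definitions; thresholded metrics
#' (accuracy, recall, precision, F1) at score 0.5, matching argmax on the
#' two-class head. Precision and F1 are 0 when no positive is predicted.
#'
#' @param y_true 0/1 labels.
#' @param scores Predicted positive-class probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector: auc, aupr, accuracy, recall, precision,
#'   f1.
#' @export
evaluate_scores <- function(y_true, scores, threshold = 0.5) {
  y <- as.integer(y_true)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(auc = auc_score(y, scores), aupr = aupr_score(y, scores),
    accuracy = mean(pred == y), recall = rec, precision = prec, f1 = f1)
}
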