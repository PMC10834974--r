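#' Closed-form classification metrics
#'
#' Standard metrics derived from a 2x2 [ConfusionMatrix-class]. Undefined
#' quantities (empty margins) are returned as \code{NA}, never as 0, so
#' degenerate folds cannot silently masquerade as perfect ones.
#'
#' \describe{
#'   \item{cmSensitivity}{TP / (TP + FN); identical to recall}
#'   \item{cmSpecificity}{TN / (TN + FP)}
#'   \item{cmAccuracy}{(TP + TN) / total}
#'   \item{cmPrecision}{TP / (TP + FP)}
#'   \item{cmF1}{harmonic mean of precision and recall}
#'   \item{cmYouden}{sensitivity + specificity - 1}
#' }
#'
#' @param cm a [ConfusionMatrix-class].
#' @return a single numeric value, or for \code{cmMetrics} a named numeric
#'   vector (sensitivity, specificity, accuracy, precision, recall, f1,
#'   youden_j).
#' @examples
#' cm <- ConfusionMatrix(26, 0, 8, 74)
#' cmSensitivity(cm)  # 26/34
#' cmMetrics(cm)
#' @name confusion-metrics
NULL

#' @rdname confusion-metrics
#' @export
cmSensitivity <- function(cm) {
  d <- cm@tp + cm@fn
  if (d == 0) NA_real_ else cm@tp / d
}

#' @rdname confusion-metrics
#' @export
cmSpecificity <- function(cm) {
  d <- cm@tn + cm@fp
  if (d == 0) NA_real_ else cm@tn / d
}

#' @rdname confusion-metrics
#' @export
cmAccuracy <- function(cm) {
  (cm@tp + cm@tn) / (cm@tp + cm@fp + cm@fn + cm@tn)
}

#' @rdname confusion-metrics
#' @export
cmPrecision <- function(cm) {
  d <- cm@tp + cm@fp
  if (d == 0) NA_real_ else cm@tp / d
}

#' @rdname confusion-metrics
#' @export
cmRecall <- function(cm) cmSensitivity(cm)

#' @rdname confusion-metrics
#' @export
cmF1 <- function(cm) {
  p <- cmPrecision(cm)
  r <- cmRecall(cm)
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' @rdname confusion-metrics
#' @export
cmYouden <- function(cm) cmSensitivity(cm) + cmSpecificity(cm) - 1

#' @rdname confusion-metrics
#' @export
cmMetrics <- function(cm) {
  c(sensitivity = cmSensitivity(cm), specificity = cmSpecificity(cm),
    accuracy = cmAccuracy(cm), precision = cmPrecision(cm),
    recall = cmRecall(cm), f1 = cmF1(cm), youden_j = cmYouden(cm))
}

#' Rank-based AUC from continuous scores
#'
#' The probability that a random positive-class score exceeds a random
#' negative-class score, with ties counting one half (the Mann-Whitney
#' statistic divided by \eqn{n_1 n_2}). Orientation is fixed by
#' \code{positive}: unlike [rankAUC()], the value may fall below 0.5 when
#' scores are anti-correlated with the labels. Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores numeric classifier scores.
#' @param labels factor or vector of class labels.
#' @param positive label of the positive class; default the last factor
#'   level.
#' @return AUC in [0, 1].
#' @examples
#' aucFromScores(c(0.1, 0.4, 0.35, 0.8), c("a", "a", "b", "b"), "b")
#' @export
aucFromScores <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  if (!positive %in% labels || all(labels == positive))
    stopf("both classes must be present to compute an AUC")
  ok <- is.finite(scores)
  scores <- scores[ok]
  labels <- labels[ok]
  pos <- labels == positive
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Confusion matrix from scores at a decision threshold
#'
#' @inheritParams aucFromScores
#' @param threshold scores \code{>= threshold} are called positive
#'   (default 0.5 on a probability scale).
#' @return a [ConfusionMatrix-class].
#' @examples
#' cmFromScores(c(0.2, 0.9, 0.6, 0.4), c("a", "b", "b", "a"), "b")
#' @export
cmFromScores <- function(scores, labels, positive = NULL, threshold = 0.5) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pred <- scores >= threshold
  actual <- labels == positive
  ConfusionMatrix(tp = sum(pred & actual), fp = sum(pred & !actual),
                  fn = sum(!pred & actual), tn = sum(!pred & !actual))
}

#' ROC curve points from scores
#'
#' Steps through the sorted unique scores as thresholds; the returned
#' polyline starts at (0, 0) and ends at (1, 1).
#'
#' @inheritParams aucFromScores
#' @return data.frame with columns \code{fpr}, \code{tpr}.
#' @export
rocCurvePoints <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}
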