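.checkTwoClasses <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute a ranking metric")
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the step-curve (average-precision) estimator: precision and recall
#' are evaluated at every distinct score threshold and the area is the sum
#' of precision times recall increment. Trapezoidal interpolation is
#' deliberately avoided -- it over-estimates PR areas. Tied scores are
#' handled by thresholding, not by an arbitrary within-tie order, so the
#' result is invariant to any strictly monotone transform of the scores.
#'
#' @param scores numeric prediction scores (higher = more positive)
#' @param labels 0/1 labels, both classes present
#' @return average precision in [0, 1]
#' @examples
#' computeAUPR(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 0.8333...
#' @export
computeAUPR <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  .checkTwoClasses(labels)
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # last index of each tied-score block = one threshold
  cut <- which(diff(s) != 0)
  idx <- c(cut, length(s))
  prec <- tp[idx] / (tp[idx] + fp[idx])
  rec <- tp[idx] / sum(y)
  sum(prec * diff(c(0, rec)))
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, ties counting one half; computed
#' from midranks.
#'
#' @inheritParams computeAUPR
#' @return AUC in [0, 1]
#' @examples
#' computeAUC(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 0.5
#' @export
computeAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  .checkTwoClasses(labels)
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Error rate from AUPR
#'
#' ER = 1 - AUPR.
#'
#' @param aupr a value in [0, 1]
#' @return the error rate, in [0, 1]
#' @examples
#' errorRate(0.92)  # 0.08
#' @export
errorRate <- function(aupr) {
  if (any(aupr < 0 | aupr > 1)) stop("AUPR must lie in [0, 1]")
  1 - aupr
}

#' Relative error-rate reduction
#'
#' The reduction of the best method's error rate relative to the second
#' best: (ER2 - ER1) / ER2.
#'
#' @param erBest error rate of the best method (ER1)
#' @param erSecond error rate of the comparator (ER2), strictly positive
#' @return relative reduction, at most 1 (negative when the "best" is worse)
#' @examples
#' deltaER(0.12, 0.16)  # 0.25
#' @export
deltaER <- function(erBest, erSecond) {
  if (any(erSecond <= 0))
    stop("relative error-rate reduction is undefined for ER2 = 0")
  (erSecond - erBest) / erSecond
}

#' Mean average precision over drugs
#'
#' Computes the average precision of each drug's target ranking and returns
#' the unweighted mean over drugs that have at least one positive (average
#' precision is undefined for the rest, so they are excluded).
#'
#' @param perDrug named list; each element a list with numeric
#'   \code{scores} and 0/1 \code{labels} over one drug's candidate targets
#' @return mean average precision in [0, 1]
#' @export
meanAveragePrecision <- function(perDrug) {
  aps <- vapply(perDrug, function(x) {
    if (sum(x$labels) == 0) return(NA_real_)
    if (all(x$labels == 1)) return(1)
    computeAUPR(x$scores, x$labels)
  }, numeric(1))
  aps <- aps[!is.na(aps)]
  if (!length(aps)) stop("no drug has a positive label")
  mean(aps)
}
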