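## Evaluation protocol: confusion counts, the standard binary metrics,
## precision-recall curves on a fixed 100-threshold grid traversed from 1
## down to 0, trapezoid AUPRC over that traversal, threshold selection at
## the precision/recall intersection, and paired bootstrap comparison of two
## scorers.
##
## The threshold grid is the 100 evenly spaced values k/99, k = 99..0. A
## nominal "step of 0.01" would give 101 values; the printed optimal
## thresholds (e.g. 0.2121 = 21/99) pin the grid to exactly 100 points.

PR_GRID <- seq(1, 0, length.out = 100)

#' Confusion counts at a threshold
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold.
#'
#' @param labels 0/1 vector of true labels.
#' @param probs Numeric scores (typically probabilities).
#' @param threshold Decision threshold.
#' @return Named integer vector: \code{TP, FP, TN, FN}.
#' @export
confusionCounts <- function(labels, probs, threshold) {
  labels <- as.integer(labels)
  pred <- probs >= threshold
  c(TP = sum(pred & labels == 1L), FP = sum(pred & labels == 0L),
    TN = sum(!pred & labels == 0L), FN = sum(!pred & labels == 1L))
}

#' Binary classification metrics from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2*Precision*Recall/(Precision+Recall),
#' Accuracy = (TP+TN)/n, Specificity = TN/(TN+FP), NPV = TN/(TN+FN).
#' Empty denominators follow the precision-recall-curve convention:
#' precision is 1 when nothing is called positive, NPV is 1 when nothing is
#' called negative; recall/specificity are NaN only when the class itself is
#' absent.
#'
#' @param cc Named counts as returned by \code{\link{confusionCounts}}.
#' @return Named numeric vector: \code{precision, recall, F1, accuracy,
#'   specificity, NPV}.
#' @export
classificationMetrics <- function(cc) {
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  precision <- if (TP + FP == 0L) 1 else TP / (TP + FP)
  recall <- TP / (TP + FN)
  npv <- if (TN + FN == 0L) 1 else TN / (TN + FN)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, F1 = f1,
    accuracy = (TP + TN) / (TP + FP + TN + FN),
    specificity = TN / (TN + FP), NPV = npv)
}

#' Precision-recall curve on the 100-threshold grid
#'
#' Slides the threshold from 1 down to 0 across the 100 grid values k/99 and
#' records precision, recall and specificity at each.
#'
#' @param labels 0/1 vector of true labels.
#' @param probs Numeric scores.
#' @return data.frame of class \code{prCurve} with columns
#'   \code{threshold, precision, recall, specificity} (threshold
#'   decreasing).
#' @export
prCurve <- function(labels, probs) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  ord <- order(probs, decreasing = TRUE)
  ps <- probs[ord]; ls <- labels[ord]
  cumTP <- cumsum(ls == 1L); cumFP <- cumsum(ls == 0L)
  ## number of samples with score >= t, via descending sorted scores
  nAt <- length(ps) - findInterval(PR_GRID, rev(ps), left.open = TRUE)
  TP <- ifelse(nAt > 0L, cumTP[pmax(nAt, 1L)], 0L)
  FP <- ifelse(nAt > 0L, cumFP[pmax(nAt, 1L)], 0L)
  out <- data.frame(
    threshold = PR_GRID,
    precision = ifelse(TP + FP == 0L, 1, TP / (TP + FP)),
    recall = TP / nPos,
    specificity = (nNeg - FP) / nNeg)
  class(out) <- c("prCurve", "data.frame")
  out
}

#' Area under the precision-recall curve (fixed-grid trapezoid)
#'
#' Trapezoid rule over the curve exactly as traversed from threshold 1 down
#' to 0: \code{sum((R[i+1] - R[i]) * (P[i+1] + P[i]) / 2)}, clipped to
#' [0, 1]. For a random (constant) scorer the value approaches the
#' positive-class prevalence.
#'
#' @param curve A \code{\link{prCurve}} data.frame (or any data.frame with
#'   \code{precision} and \code{recall} ordered by decreasing threshold).
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(curve) {
  r <- curve$recall; p <- curve$precision
  n <- length(r)
  a <- sum((r[-1] - r[-n]) * (p[-1] + p[-n]) / 2)
  min(max(a, 0), 1)
}

#' Optimal threshold at the precision/recall intersection
#'
#' Returns the grid threshold minimizing |precision - recall|; ties are
#' broken toward the larger F1, then the smaller threshold. The reported
#' metrics are those of the selected grid point.
#'
#' @param curve A \code{\link{prCurve}} data.frame.
#' @return List: \code{threshold}, \code{precision}, \code{recall},
#'   \code{specificity}, \code{F1}.
#' @export
optimalThreshold <- function(curve) {
  gap <- abs(curve$precision - curve$recall)
  f1 <- ifelse(curve$precision + curve$recall == 0, 0,
               2 * curve$precision * curve$recall /
                 (curve$precision + curve$recall))
  cand <- which(gap <= min(gap) + 1e-12)
  cand <- cand[f1[cand] >= max(f1[cand]) - 1e-12]
  k <- cand[which.min(curve$threshold[cand])]
  list(threshold = curve$threshold[k], precision = curve$precision[k],
       recall = curve$recall[k], specificity = curve$specificity[k],
       F1 = f1[k])
}

#' Paired bootstrap comparison of two scorers
#'
#' Resamples the test set with replacement at full size for the given number
#' of iterations, computes the grid AUPRC of both scorers on every resample,
#' and reports the mean AUPRC difference (A minus B), the one-sided p-value
#' (the proportion of resamples where the difference was less than or equal
#' to zero — so two identical scorers give p = 1 under this convention), and
#' 95 percent percentile confidence intervals per scorer. Resamples missing
#' a class are redrawn (and counted).
#'
#' @param labels 0/1 vector of true labels.
#' @param probsA,probsB Scores of the two methods on the same samples.
#' @param iterations Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return List: \code{meanDiff}, \code{pValue}, \code{ciA}, \code{ciB},
#'   \code{auprcA}, \code{auprcB}, \code{pctDiffMean} (100 * meanDiff /
#'   auprcB), \code{pctDiffPoint} (100 * (auprcA - auprcB) / auprcB — the two
#'   ways a relative AUPRC difference is commonly quoted), \code{iterations},
#'   \code{redraws}, \code{seed}.
#' @export
bootstrapCompare <- function(labels, probsA, probsB, iterations = 1000L,
                             seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(length(probsA) == n, length(probsB) == n)
  set.seed(seed)
  dA <- numeric(iterations); dB <- numeric(iterations)
  redraws <- 0L
  for (it in seq_len(iterations)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    dA[it] <- auprc(prCurve(labels[idx], probsA[idx]))
    dB[it] <- auprc(prCurve(labels[idx], probsB[idx]))
  }
  diffs <- dA - dB
  aA <- auprc(prCurve(labels, probsA))
  aB <- auprc(prCurve(labels, probsB))
  list(meanDiff = mean(diffs),
       pValue = mean(diffs <= 0),
       ciA = unname(stats::quantile(dA, c(0.025, 0.975))),
       ciB = unname(stats::quantile(dB, c(0.025, 0.975))),
       auprcA = aA, auprcB = aB,
       pctDiffMean = if (aB > 0) 100 * mean(diffs) / aB else NA_real_,
       pctDiffPoint = if (aB > 0) 100 * (aA - aB) / aB else NA_real_,
       iterations = as.integer(iterations), redraws = redraws,
       seed = as.integer(seed))
}
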