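#' Confusion counts for binary predictions
#'
#' The positive class is mRNA (label 1) throughout.
#'
#' @param labels binary vector of true labels (0/1).
#' @param predicted binary vector of predicted labels (0/1).
#' @return Named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(labels, predicted) {
    if (length(labels) != length(predicted))
        stop("'labels' and 'predicted' must have equal length")
    if (!length(labels)) stop("empty input")
    labels <- as.integer(labels); predicted <- as.integer(predicted)
    if (!all(labels %in% 0:1) || !all(predicted %in% 0:1))
        stop("labels and predictions must be binary 0/1")
    c(TP = sum(labels == 1L & predicted == 1L),
      FP = sum(labels == 0L & predicted == 1L),
      TN = sum(labels == 0L & predicted == 0L),
      FN = sum(labels == 1L & predicted == 0L))
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 P R / (P + R), accuracy = (TP+TN)/total. Undefined ratios
#' (zero denominators) return 0 with a warning.
#'
#' @param counts named vector from [confusionCounts()].
#' @return Named numeric vector `precision`, `recall`, `f1`, `accuracy`.
#' @export
summaryMetrics <- function(counts) {
    safe <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (zero denominator); returning 0")
            return(0)
        }
        num / den
    }
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    tn <- counts[["TN"]]; fn <- counts[["FN"]]
    precision <- safe(tp, tp + fp, "precision")
    recall <- safe(tp, tp + fn, "recall")
    f1 <- if (precision + recall == 0) {
        warning("F1 undefined (precision + recall = 0); returning 0")
        0
    } else 2 * precision * recall / (precision + recall)
    accuracy <- (tp + tn) / (tp + fp + tn + fn)
    c(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct prediction scores
#' (grouping tied scores at a single threshold), computing the true
#' positive rate TP/(TP+FN) and false positive rate FP/(FP+TN) at each,
#' and integrates the curve by the trapezoidal rule. The resulting area
#' equals the rank-based estimator
#' \eqn{P(s^+ > s^-) + \frac12 P(s^+ = s^-)} over positive/negative pairs.
#'
#' @param labels binary vector (1 = mRNA, the positive class).
#' @param scores numeric prediction scores (higher means more mRNA-like).
#' @return A [RocCurve-class].
#' @export
rocAuc <- function(labels, scores) {
    if (length(labels) != length(scores))
        stop("'labels' and 'scores' must have equal length")
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to form a ROC curve")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- labels[ord]
    tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
    last <- which(c(s[-1L] != s[-length(s)], TRUE))  # end of each tie group
    tpr <- c(0, tp[last] / nPos, 1)
    fpr <- c(0, fp[last] / nNeg, 1)
    auroc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
    new("RocCurve", fpr = fpr, tpr = tpr, auroc = auroc)
}

#' Evaluate predicted probabilities against labels
#'
#' Thresholds the probabilities at 0.5 and reports the five standard
#' figures of merit.
#'
#' @param labels binary vector (1 = mRNA).
#' @param prob numeric predicted mRNA probabilities.
#' @return Named numeric vector `precision`, `recall`, `f1`, `accuracy`,
#'   `auroc`.
#' @export
evaluatePredictions <- function(labels, prob) {
    cc <- confusionCounts(labels, as.integer(prob >= 0.5))
    c(summaryMetrics(cc), auroc = rocAuc(labels, prob)@auroc)
}
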