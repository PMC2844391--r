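#' Classification metrics from a confusion matrix
#'
#' Precision, recall (sensitivity / TP rate), false positive rate, F1
#' (harmonic mean of precision and recall) and the Matthews correlation
#' coefficient. Any metric whose denominator is zero is defined as 0
#' (including the MCC).
#'
#' @param tPos,tNeg,fPos,fNeg confusion-matrix counts
#' @return named numeric vector \code{c(precision, recall, fpr, f1, mcc)}
#' @examples
#' confusionMetrics(tPos = 3, tNeg = 83, fPos = 7, fNeg = 7)
#' @export
confusionMetrics <- function(tPos, tNeg, fPos, fNeg) {
  stopifnot(tPos >= 0, tNeg >= 0, fPos >= 0, fNeg >= 0)
  precision <- if (tPos + fPos > 0) tPos / (tPos + fPos) else 0
  recall <- if (tPos + fNeg > 0) tPos / (tPos + fNeg) else 0
  fpr <- if (fPos + tNeg > 0) fPos / (fPos + tNeg) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  den <- sqrt(as.numeric(tPos + fPos)) * sqrt(as.numeric(tPos + fNeg)) *
    sqrt(as.numeric(tNeg + fPos)) * sqrt(as.numeric(tNeg + fNeg))
  mcc <- if (den > 0)
    (as.numeric(tPos) * tNeg - as.numeric(fPos) * fNeg) / den else 0
  c(precision = precision, recall = recall, fpr = fpr, f1 = f1, mcc = mcc)
}

#' Metrics from predicted and true labels
#'
#' @param predicted,truth vectors of +1/-1 labels
#' @return as \code{\link{confusionMetrics}}
#' @export
labelMetrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusionMetrics(
    tPos = sum(predicted == 1 & truth == 1),
    tNeg = sum(predicted == -1 & truth == -1),
    fPos = sum(predicted == 1 & truth == -1),
    fNeg = sum(predicted == -1 & truth == 1))
}

# per-protein ROC points from a score ranking; ties share a threshold
rocPoints <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; label <- label[ord]
  nP <- sum(label == 1); nN <- sum(label == -1)
  cumTP <- cumsum(label == 1)
  cumFP <- cumsum(label == -1)
  last <- !duplicated(score, fromLast = TRUE)  # rightmost index per tie block
  data.frame(fpr = c(0, cumFP[last] / nN), tpr = c(0, cumTP[last] / nP))
}

rpPoints <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; label <- label[ord]
  nP <- sum(label == 1)
  cumTP <- cumsum(label == 1)
  prec <- cumTP / seq_along(label)
  last <- !duplicated(score, fromLast = TRUE)
  data.frame(recall = cumTP[last] / nP, precision = prec[last])
}

# Interpolate the ROC corner polyline onto a fixed FPR grid. Between
# distinct FPR nodes the curve runs from the top of the left node to the
# bottom of the right node (horizontal for untied rankings, diagonal only
# across tie blocks); at a node the curve takes the node's maximal TPR.
interpROC <- function(pts, grid) {
  x <- pts$fpr
  y <- pts$tpr
  ux <- unique(x)  # non-decreasing in threshold order
  fx <- factor(x, levels = ux)
  yHigh <- as.numeric(tapply(y, fx, max))
  yLow <- as.numeric(tapply(y, fx, min))
  k <- findInterval(grid, ux)
  k <- pmax(k, 1L)
  kNext <- pmin(k + 1L, length(ux))
  den <- ux[kNext] - ux[k]
  den[den == 0] <- 1
  frac <- (grid - ux[k]) / den
  out <- yHigh[k] + (yLow[kNext] - yHigh[k]) * frac
  atNode <- abs(grid - ux[k]) < 1e-12
  out[atNode] <- yHigh[k][atNode]
  out[k >= length(ux)] <- yHigh[length(ux)]
  out
}

# rightmost-precision (maximum-over-higher-recall) interpolation
interpRP <- function(pts, grid) {
  o <- order(pts$recall)
  r <- pts$recall[o]; p <- pts$precision[o]
  pMaxRight <- rev(cummax(rev(p)))
  idx <- findInterval(grid, r, left.open = TRUE) + 1L
  out <- ifelse(idx <= length(r), pMaxRight[pmin(idx, length(r))], 0)
  out
}

averagedCurve <- function(scored, type = c("roc", "rp"), gridStep = 0.01) {
  type <- match.arg(type)
  stopifnot(all(c("protein", "score", "label") %in% names(scored)))
  grid <- seq(0, 1, by = gridStep)
  curves <- list()
  for (p in unique(scored$protein)) {
    sub <- scored[scored$protein == p, ]
    if (!any(sub$label == 1) || !any(sub$label == -1)) {
      warning(sprintf(
        "protein %s lacks a positive or negative residue; excluded from curve averaging", p))
      next
    }
    curves[[p]] <- if (type == "roc")
      interpROC(rocPoints(sub$score, sub$label), grid)
    else interpRP(rpPoints(sub$score, sub$label), grid)
  }
  if (!length(curves))
    stop("no protein with both classes; cannot average curves")
  mat <- do.call(rbind, curves)
  mean_y <- colMeans(mat)
  auc <- sum(diff(grid) * (head(mean_y, -1) + mean_y[-1]) / 2)
  list(curve = data.frame(grid = grid, mean = mean_y),
       auc = auc, nProteins = length(curves))
}

#' Per-protein averaged ROC curve and area
#'
#' Computes the ROC curve of each protein from its score ranking (tied
#' scores share a threshold), interpolates every curve onto a fixed FPR
#' grid (0 to 1, step \code{gridStep}), averages the true-positive rates
#' pointwise across proteins and reports the area under the averaged curve
#' (trapezoid rule). Proteins without at least one positive and one
#' negative residue are excluded with a warning, since their ROC is
#' undefined.
#'
#' @param scored data.frame with columns \code{protein}, \code{score}
#'   (higher = more likely catalytic) and \code{label} (+1/-1)
#' @param gridStep grid resolution (default 0.01)
#' @return list with \code{curve} (data.frame grid, mean), \code{auc} and
#'   \code{nProteins}
#' @export
averagedROC <- function(scored, gridStep = 0.01) {
  averagedCurve(scored, "roc", gridStep)
}

#' Per-protein averaged recall-precision curve and area
#'
#' As \code{\link{averagedROC}} but on a recall grid; precision at a grid
#' recall r is the maximum precision attained at any recall >= r
#' (rightmost-precision interpolation), which makes the per-protein curve
#' monotone and well defined on the whole grid. For the strongly skewed
#' catalytic-residue task this area is more informative than the ROC area.
#'
#' @inheritParams averagedROC
#' @return list with \code{curve}, \code{auc} and \code{nProteins}
#' @export
averagedRP <- function(scored, gridStep = 0.01) {
  averagedCurve(scored, "rp", gridStep)
}

#' Paired Wilcoxon signed-rank test on per-fold F1
#'
#' Two-sided paired Wilcoxon test between the per-fold F1 values of two
#' configurations, at confidence level \code{alpha}. Zero differences are
#' dropped (standard treatment); if all differences are zero the result is
#' p = 1, not significant. For the small sample sizes typical of k-fold
#' comparisons (up to 14 non-zero differences) the exact null is obtained
#' by enumerating all sign assignments, which stays exact in the presence
#' of tied absolute differences (midranks); larger samples use the normal
#' approximation with continuity correction.
#'
#' @param f1A,f1B numeric vectors of per-fold F1 (equal length >= 5)
#' @param alpha significance level (default 0.05)
#' @return list with \code{pValue}, \code{significant}, \code{nUsed}
#' @export
wilcoxonF1 <- function(f1A, f1B, alpha = 0.05) {
  stopifnot(length(f1A) == length(f1B), length(f1A) >= 5)
  d <- f1A - f1B
  d <- d[d != 0]
  if (!length(d))
    return(list(pValue = 1, significant = FALSE, nUsed = 0L))
  n <- length(d)
  if (n <= 14L) {
    r <- rank(abs(d))  # midranks for ties
    obs <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    stats <- vapply(0:(2^n - 1), function(mask) {
      signs <- as.integer(intToBits(mask))[seq_len(n)]
      sum(r[signs == 1L])
    }, numeric(1))
    p <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                         exact = FALSE, correct = TRUE)$p.value)
  }
  list(pValue = p, significant = p < alpha, nUsed = n)
}

#' Negative-to-positive class ratio
#'
#' The "1:n" imbalance of a labeled dataset: number of negative examples
#' per positive example.
#'
#' @param labels vector of +1/-1 labels, or a labels data.frame with a
#'   \code{label} column
#' @return negatives / positives (Inf when no positive)
#' @export
classImbalanceRatio <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == -1)
  if (nPos == 0) return(Inf)
  nNeg / nPos
}
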