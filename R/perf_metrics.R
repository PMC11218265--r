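# Per-combination performance measures: the area under the balanced
# precision-recall curve for binary traits, and the squared Pearson
# correlation of variant scores with variant-mean trait values for
# quantitative traits.
#
# Balanced precision rescales precision to a 50% prior on positives:
# TPR / (TPR + FPR). The curve is built over all distinct participant-score
# thresholds in descending order (tied scores move together), anchored at
# recall 0 by constant extension of the first achieved point, and
# integrated over recall by the trapezoidal rule. This construction is
# invariant to strictly increasing transforms of the scores.

#' Confusion counts at a score threshold
#'
#' Predicted positives are participants with score `>= s`; true positives
#' additionally have the trait.
#'
#' @param scores numeric participant scores.
#' @param labels 0/1 trait labels, same length.
#' @param s threshold.
#' @return list with TP, FP, FN, TN, P, N, PP.
#' @export
confusion_at_threshold <- function(scores, labels, s) {
  vb_check(length(scores) == length(labels),
           "scores and labels must have equal length")
  pp <- scores >= s
  tp <- sum(pp & labels == 1)
  fp <- sum(pp & labels == 0)
  p <- sum(labels == 1); n <- sum(labels == 0)
  list(TP = tp, FP = fp, FN = p - tp, TN = n - fp,
       P = p, N = n, PP = tp + fp)
}

#' Balanced precision of a confusion
#'
#' The precision expected in an evaluation set with equal numbers of
#' positives and negatives: `TPR / (TPR + FPR)`. Requires both classes
#' present; returns `NA` (the undefined-metric signal consumed by the
#' bootstrap layer) when `P` or `N` is zero, and `NaN` for an unachieved
#' threshold (TP = FP = 0), which the curve construction never integrates.
#'
#' @param conf result of [confusion_at_threshold()].
#' @return value in `[0, 1]`, or NA/NaN as above.
#' @export
balanced_precision <- function(conf) {
  if (conf$P == 0 || conf$N == 0) return(NA_real_)
  tpr <- conf$TP / conf$P
  fpr <- conf$FP / conf$N
  if (tpr + fpr == 0) return(NaN)
  tpr / (tpr + fpr)
}

#' Area under the balanced precision-recall curve
#'
#' Thresholds are the distinct observed scores in descending order; the
#' lowest threshold predicts every participant positive (recall 1). The
#' point at recall 0 is the constant extension of the balanced precision at
#' the most stringent achieved threshold. Integration is trapezoidal over
#' recall. Returns `NA` when the evaluation set has a single class.
#'
#' @param scores numeric participant scores.
#' @param labels 0/1 trait labels.
#' @return area in `[0, 1]`, or NA when undefined.
#' @export
aubprc <- function(scores, labels) {
  vb_check(length(scores) == length(labels) && length(scores) > 0,
           "scores and labels must be non-empty and of equal length")
  p <- sum(labels == 1); n <- sum(labels == 0)
  if (p == 0 || n == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  m <- length(s)
  # last index of each tie group = cumulative counts at each distinct score
  keep <- c(s[-m] != s[-1], TRUE)
  tp <- cumsum(l == 1)[keep]
  ppos <- seq_len(m)[keep]
  fp <- ppos - tp
  tpr <- tp / p
  fpr <- fp / n
  bp <- tpr / (tpr + fpr)   # ppos >= 1 so tpr + fpr > 0 at every threshold
  recall <- c(0, tpr)
  bp <- c(bp[1], bp)
  sum(diff(recall) * (bp[-1] + bp[-length(bp)]) / 2)
}

#' Squared Pearson correlation
#'
#' `PCC^2` gives equal weight to positive and negative correlations of
#' similar strength. Returns `NA` (undefined-metric signal) when fewer than
#' three pairs remain or either input has zero variance.
#'
#' @param x,y numeric vectors of equal length (pairs with NA in either are
#'   dropped).
#' @return value in `[0, 1]`, or NA when undefined.
#' @export
squared_pearson <- function(x, y) {
  vb_check(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# Vectorized column-wise PCC^2 of a fixed score vector against each column
# of a matrix of (possibly NA) variant-mean trait values. Used by the
# bootstrap engine; per-column NA masks are handled without looping.
colwise_pcc2 <- function(x, m) {
  ok <- is.finite(m)
  m0 <- m; m0[!ok] <- 0
  ni <- colSums(ok)
  sx <- colSums(x * ok); sxx <- colSums(x^2 * ok)
  sy <- colSums(m0); syy <- colSums(m0^2); sxy <- colSums(x * m0)
  sxy_c <- sxy - sx * sy / ni
  vx <- sxx - sx^2 / ni
  vy <- syy - sy^2 / ni
  tol_x <- pmax(sxx, 1) * 1e-12
  tol_y <- pmax(syy, 1) * 1e-12
  r2 <- ifelse(ni >= 3 & vx > tol_x & vy > tol_y,
               sxy_c^2 / (vx * vy), NA_real_)
  pmin(r2, 1)
}
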