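# Ordinal label coding, the two loss heads, the joint objective, and the
# evaluation metrics (accuracy, quadratic weighted kappa, one-vs-rest AUC,
# confusion counts).

#' Encode a severity grade as rank-threshold bits
#'
#' Recasts a K-grade ordinal label as K-1 binary sub-task labels, bit k
#' answering "is the grade strictly greater than k-1?" (1-based k). The
#' resulting bit vector is always non-increasing left to right.
#'
#' @param grade integer grade in `0:(K-1)` (vectorised).
#' @param K number of ordinal classes (default 5).
#' @return for a single grade, an integer vector of length `K-1`; for a
#'   vector of grades, a matrix with one row per grade.
#' @examples
#' encodeOrdinal(2, K = 5)  # 1 1 0 0
#' @export
encodeOrdinal <- function(grade, K = 5L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (any(grade < 0L | grade > K - 1L) || any(grade != floor(grade)))
    stop("grade must be an integer in [0, K-1]")
  thr <- 0:(K - 2L)
  if (length(grade) == 1L) return(as.integer(grade > thr))
  t(vapply(grade, function(g) as.integer(g > thr), integer(K - 1L)))
}

#' Decode rank-threshold probabilities back to a grade
#'
#' The default rule counts sub-task probabilities exceeding the threshold,
#' which is the standard rank-consistent aggregation and is well defined
#' even when the probability vector is not monotone. The alternative
#' `"first"` rule stops at the first sub-task that fails.
#'
#' @param q numeric vector of K-1 sub-task probabilities in [0,1].
#' @param threshold decision threshold (default 0.5).
#' @param method `"count"` (default) or `"first"` (index of first failure).
#' @return integer grade in `0:(K-1)`.
#' @export
decodeOrdinal <- function(q, threshold = 0.5, method = c("count", "first")) {
  method <- match.arg(method)
  if (length(q) == 0L) stop("q must be non-empty")
  if (any(q < 0 | q > 1)) stop("q values must lie in [0, 1]")
  if (method == "count") return(as.integer(sum(q > threshold)))
  fails <- which(q <= threshold)
  if (length(fails) == 0L) length(q) else as.integer(fails[1L] - 1L)
}

# Stable row-wise log-softmax.
logSoftmaxRows <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

#' Label-smoothed cross-entropy classification loss
#'
#' Softmax cross-entropy against a one-hot target smoothed to `1 - eps` on
#' the true class and `eps / (K - 1)` elsewhere, averaged over the batch.
#' Optional per-class costs rescale each sample's loss by
#' `classCosts[grade] / mean(classCosts[grades in batch])`, a cost-sensitive
#' reweighting to counter majority-class bias; off by default.
#'
#' @param logits numeric vector of K logits, or an N x K matrix.
#' @param grade integer grade(s) in `0:(K-1)`, length N.
#' @param eps label smoothing mass in `[0, 1)` (default 0.1).
#' @param classCosts optional positive numeric vector of length K.
#' @return non-negative scalar loss (batch mean).
#' @export
classificationLoss <- function(logits, grade, eps = 0.1, classCosts = NULL) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  checkFinite(logits, "logits")
  K <- ncol(logits)
  if (eps < 0 || eps >= 1) stop("eps must lie in [0, 1)")
  if (any(grade < 0L | grade > K - 1L)) stop("grade out of range")
  if (!is.null(classCosts) &&
      (length(classCosts) != K || any(classCosts <= 0)))
    stop("classCosts must be K positive values")
  lp <- logSoftmaxRows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), grade + 1L)
  # -sum target * logp with smoothed target
  per <- -((1 - eps) * lp[idx] + (eps / (K - 1)) * (rowSums(lp) - lp[idx]))
  if (!is.null(classCosts)) {
    cost <- classCosts[grade + 1L]
    per <- per * cost / mean(cost)
  }
  mean(per)
}

# Gradient of classificationLoss w.r.t. logits (N x K), batch-mean reduced.
classificationLossGrad <- function(logits, grade, eps = 0.1,
                                   classCosts = NULL) {
  K <- ncol(logits)
  n <- nrow(logits)
  p <- softmaxRows(logits)
  target <- matrix(eps / (K - 1), n, K)
  target[cbind(seq_len(n), grade + 1L)] <- 1 - eps
  g <- p - target
  if (!is.null(classCosts)) {
    cost <- classCosts[grade + 1L]
    g <- g * (cost / mean(cost))
  }
  g / n
}

#' Binary cross-entropy ordinal loss
#'
#' Sum over the K-1 rank sub-tasks of the binary cross-entropy between
#' `sigmoid(ordLogits)` and the rank-threshold bits, averaged over the
#' batch. Computed from logits in a numerically stable form.
#'
#' @param ordLogits numeric vector of K-1 logits, or an N x (K-1) matrix.
#' @param target bits from [encodeOrdinal()] (vector or matching matrix).
#' @return non-negative scalar loss (batch mean of per-sample sums).
#' @export
ordinalLoss <- function(ordLogits, target) {
  if (is.null(dim(ordLogits))) {
    ordLogits <- matrix(ordLogits, nrow = 1L)
    target <- matrix(target, nrow = 1L)
  }
  checkFinite(ordLogits, "ordinal logits")
  if (!all(dim(ordLogits) == dim(target)))
    stop("ordLogits and target shapes disagree")
  if (any(target != 0 & target != 1)) stop("target bits must be 0/1")
  z <- ordLogits; v <- target
  per <- pmax(z, 0) - z * v + log1p(exp(-abs(z)))
  mean(rowSums(per))
}

# Gradient of ordinalLoss w.r.t. ordLogits, batch-mean reduced.
ordinalLossGrad <- function(ordLogits, target) {
  (sigmoid(ordLogits) - target) / nrow(ordLogits)
}

#' Joint dual-head objective
#'
#' Convex mixture `lambda * lcls + (1 - lambda) * lord` of the
#' classification and ordinal losses. `lambda = 0.5` balances the heads;
#' the degenerate ends recover each head alone.
#'
#' @param lcls classification loss (non-negative scalar).
#' @param lord ordinal loss (non-negative scalar).
#' @param lambda mixing weight in `[0, 1]` (default 0.5).
#' @return scalar joint loss.
#' @export
jointLoss <- function(lcls, lord, lambda = 0.5) {
  if (!is.finite(lcls) || !is.finite(lord)) stop("losses must be finite")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  lambda * lcls + (1 - lambda) * lord
}

#' Exact-match accuracy
#'
#' Fraction of samples whose predicted grade equals the true grade
#' (multi-class exact match, equivalent to micro-averaged accuracy).
#'
#' @param true,pred equal-length integer grade vectors.
#' @return fraction in `[0, 1]`.
#' @export
accuracyScore <- function(true, pred) {
  if (length(true) == 0L || length(true) != length(pred))
    stop("true and pred must be non-empty and of equal length")
  mean(true == pred)
}

#' Confusion matrix of grade counts
#'
#' @param true,pred integer grade vectors in `0:(K-1)`.
#' @param K number of classes.
#' @return K x K integer matrix, rows = true grade, columns = predicted.
#' @export
confusionCounts <- function(true, pred, K = 5L) {
  if (length(true) == 0L || length(true) != length(pred))
    stop("true and pred must be non-empty and of equal length")
  if (any(c(true, pred) < 0L | c(true, pred) > K - 1L))
    stop("labels out of [0, K-1]")
  lv <- 0:(K - 1L)
  tab <- table(factor(true, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(tab), K, K,
              dimnames = list(true = lv, pred = lv))
  m
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement with squared-distance penalties:
#' `1 - sum(w * O) / sum(w * E)` with `w[i,j] = (i - j)^2`, `O` the observed
#' confusion counts and `E` the outer product of the marginals scaled to the
#' same total. (A `(K-1)^2` normalization of `w` cancels in the ratio and is
#' omitted.) When all labels on both sides are identical and agree, the
#' chance term vanishes together with the disagreement term and kappa is 1
#' by convention.
#'
#' @param true,pred integer grade vectors in `0:(K-1)`, length >= 2.
#' @param K number of classes.
#' @return kappa in `[-1, 1]`.
#' @export
quadraticWeightedKappa <- function(true, pred, K = 5L) {
  if (length(true) < 2L) stop("need at least two samples")
  O <- confusionCounts(true, pred, K)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  idx <- 0:(K - 1L)
  w <- outer(idx, idx, function(i, j) (i - j)^2)
  num <- sum(w * O)
  den <- sum(w * E)
  if (den == 0) {
    if (num == 0) return(1)
    stop("quadratic weighted kappa undefined: zero expected disagreement")
  }
  1 - num / den
}

# Midrank AUC for a binary split; returns NA when one side is empty.
binaryAUC <- function(pos, score) {
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC by the midrank statistic (ties count one half), treating
#' each class in turn as positive; micro-average pools the binarized
#' labels and scores of all classes; macro-average is the unweighted mean
#' over classes present in `true`. Classes with no positive (or no
#' negative) sample get an `NA` AUC with a warning and are excluded from
#' the macro mean.
#'
#' @param true integer grade vector in `0:(K-1)`.
#' @param scores N x K matrix of class scores (higher = more confident).
#' @return list with elements `perClass` (length K), `micro`, `macro`.
#' @export
oneVsRestAUC <- function(true, scores) {
  if (is.null(dim(scores))) stop("scores must be an N x K matrix")
  checkFinite(scores, "scores")
  K <- ncol(scores)
  n <- nrow(scores)
  if (length(true) != n) stop("true and scores disagree in length")
  per <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- true == (k - 1L)
    if (!any(pos) || all(pos)) {
      warning(sprintf("class %d has no positives or no negatives; AUC undefined",
                      k - 1L))
      next
    }
    per[k] <- binaryAUC(pos, scores[, k])
  }
  bin <- matrix(0L, n, K)
  bin[cbind(seq_len(n), true + 1L)] <- 1L
  micro <- binaryAUC(as.vector(bin) == 1L, as.vector(scores))
  macro <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  list(perClass = per, micro = micro, macro = macro)
}
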