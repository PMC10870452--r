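#' Confusion counts and classification metrics
#'
#' Computes TP/TN/FP/FN and the derived ratios
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, `Sen = TP / (TP + FN)` and
#' `Spe = TN / (TN + FP)`. A ratio with a zero denominator is reported as
#' `NaN` together with a defined-flag, never silently as 0.
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels, same length.
#' @return list with `TP`, `TN`, `FP`, `FN`, `acc`, `sen`, `spe`,
#'   `senDefined`, `speDefined`.
#' @export
computeMetrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(all(pred %in% 0:1), all(truth %in% 0:1))
  TP <- sum(pred == 1L & truth == 1L)
  TN <- sum(pred == 0L & truth == 0L)
  FP <- sum(pred == 1L & truth == 0L)
  FN <- sum(pred == 0L & truth == 1L)
  sen <- if (TP + FN > 0) TP / (TP + FN) else NaN
  spe <- if (TN + FP > 0) TN / (TN + FP) else NaN
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       acc = (TP + TN) / length(pred), sen = sen, spe = spe,
       senDefined = TP + FN > 0, speDefined = TN + FP > 0)
}

#' ROC curve and AUC by threshold sweep
#'
#' Builds the ROC curve by sweeping every distinct score threshold
#' (ties grouped), with `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`,
#' and integrates it by the trapezoidal rule. With ties handled by grouping,
#' the result equals the Mann-Whitney concordance probability
#' (ties counted 1/2).
#'
#' @param scores real-valued scores, larger meaning more seizure-like.
#' @param truth true 0/1 labels; both classes must be present.
#' @return list with `roc` (data.frame of `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
rocAuc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have the same length")
  nPos <- sum(truth == 1L); nNeg <- sum(truth == 0L)
  if (nPos == 0 || nNeg == 0)
    stop("ROC requires both classes to be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  cumTP <- cumsum(y == 1L)
  cumFP <- cumsum(y == 0L)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, cumTP[last] / nPos, 1)
  fpr <- c(0, cumFP[last] / nNeg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' K-fold split with stratification and recording-level grouping
#'
#' Produces k disjoint test folds covering all indices, with sizes differing
#' by at most one. Stratified splitting preserves the class ratio per fold
#' within one window. With `groups` given (e.g. the source recording of
#' each window), all members of a group land in one fold, which prevents
#' within-recording leakage between training and test data.
#'
#' @param labels 0/1 labels (used for stratification; also defines n).
#' @param k number of folds, `2 <= k <= n`.
#' @param seed RNG seed for the shuffle.
#' @param stratified preserve class ratios per fold (default TRUE; ignored
#'   when `groups` is given).
#' @param groups optional group id per index (recording-level splitting).
#' @return list of k elements, each `list(train = ..., test = ...)` index
#'   vectors.
#' @export
kfoldSplit <- function(labels, k = 5, seed = 1L, stratified = TRUE,
                       groups = NULL) {
  n <- length(labels)
  if (k > n) stop("k = ", k, " exceeds the number of windows (", n, ")")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(groups)) {
    ug <- unique(groups)
    if (k > length(ug)) stop("k exceeds the number of groups")
    gf <- rep_len(seq_len(k), length(ug))[sample.int(length(ug))]
    fold <- gf[match(groups, ug)]
  } else if (stratified) {
    offset <- 0L  # rotate leftovers across classes so fold sizes differ by <= 1
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (k > length(idx))
        stop("stratified split impossible: class ", cls, " has fewer than k members")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}
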