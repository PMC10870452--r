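#' Training configuration
#'
#' @param epochs number of passes over the training set (default 30).
#' @param batchSize minibatch size (default 32).
#' @param learningRate Adam step size (default 1e-3).
#' @param kFolds number of cross-validation folds (default 5; 3, 6, 9, 12
#'   and 15 are also supported protocol choices).
#' @param seed integer RNG seed; fixes shuffling and initialization so a
#'   run is reproducible on one thread.
#' @param stratified preserve the class ratio in each fold (default TRUE).
#' @return a validated list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 30, batchSize = 32, learningRate = 1e-3,
                        kFolds = 5, seed = 1L, stratified = TRUE) {
  if (kFolds < 2) stop("kFolds must be >= 2")
  if (learningRate < 0) stop("learningRate must be >= 0")
  if (epochs < 1 || batchSize < 1) stop("epochs and batchSize must be >= 1")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, kFolds = as.integer(kFolds),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "TrainConfig")
}

# recursive zero-like copy of a nested weight list
.zeroLike <- function(w) {
  if (is.list(w)) lapply(w, .zeroLike) else w * 0
}

.addGrad <- function(acc, g) {
  if (is.list(acc)) mapply(.addGrad, acc, g, SIMPLIFY = FALSE) else acc + g
}

.scaleGrad <- function(g, s) {
  if (is.list(g)) lapply(g, .scaleGrad, s = s) else g * s
}

# one Adam step over the nested structures; returns list(w, m, v)
.adamStep <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(w)) {
    out <- mapply(.adamStep, w, g, m, v,
                  MoreArgs = list(lr = lr, t = t, beta1 = beta1,
                                  beta2 = beta2, eps = eps),
                  SIMPLIFY = FALSE)
    list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
}

.asSequenceList <- function(seqs) {
  if (is.list(seqs)) return(lapply(seqs, as.matrix))
  if (length(dim(seqs)) == 3)
    return(lapply(seq_len(dim(seqs)[3]), function(i) seqs[, , i]))
  stop("sequences must be a list of matrices or a 3-D array")
}

#' Train the LTY-CNN with quantization-aware updates
#'
#' Minimizes the softmax cross-entropy with Adam. The quantizers in the
#' dilated layer are active in every forward pass and bypassed with
#' straight-through (identity) gradients in the backward pass, so the
#' weights adapt to their quantized representation during training. Input
#' sequences are divided by the training-set standard deviation (stored in
#' the model) before the forward pass.
#'
#' @param seqs list of seqLen x inputDim matrices (or a 3-D array with the
#'   window index last), one per labelled window.
#' @param labels integer 0/1 class labels, one per sequence; both classes
#'   must be present.
#' @param config a [ModelConfig-class].
#' @param tconfig a [trainConfig()].
#' @return a [TrainedModel-class] carrying the weights, the input scale and
#'   the per-epoch mean training loss.
#' @export
trainModel <- function(seqs, labels, config = modelConfig(),
                       tconfig = trainConfig()) {
  seqs <- .asSequenceList(seqs)
  labels <- as.integer(labels)
  stopifnot(length(seqs) == length(labels))
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes")
  set.seed(tconfig$seed)
  scale <- stats::sd(unlist(lapply(seqs, as.vector)))
  if (!is.finite(scale) || scale == 0) scale <- 1
  seqs <- lapply(seqs, function(s) s / scale)

  w <- initWeights(config, seed = tconfig$seed)
  m <- .zeroLike(w); v <- .zeroLike(w)
  n <- length(seqs)
  step <- 0L
  lossCurve <- numeric(tconfig$epochs)
  for (epoch in seq_len(tconfig$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    for (b0 in seq(1, n, by = tconfig$batchSize)) {
      batch <- ord[b0:min(b0 + tconfig$batchSize - 1, n)]
      gsum <- NULL
      for (i in batch) {
        cache <- .forwardCache(seqs[[i]], config, w)
        p <- exp(cache$logits - max(cache$logits))
        p <- p / sum(p)
        y <- labels[i] + 1L
        epochLoss <- epochLoss - log(max(p[y], 1e-12))
        dlogits <- p
        dlogits[y] <- dlogits[y] - 1
        g <- .backward(cache, config, w, dlogits)
        gsum <- if (is.null(gsum)) g else .addGrad(gsum, g)
      }
      gmean <- .scaleGrad(gsum, 1 / length(batch))
      step <- step + 1L
      st <- .adamStep(w, gmean, m, v, tconfig$learningRate, step)
      w <- st$w; m <- st$m; v <- st$v
    }
    lossCurve[epoch] <- epochLoss / n
  }
  new("TrainedModel", config = config, weights = w, inputScale = scale,
      lossCurve = lossCurve)
}

#' Class probabilities from a trained model
#'
#' @param model a [TrainedModel-class].
#' @param seqs list of seqLen x inputDim matrices (or 3-D array).
#' @return n x nClasses matrix of softmax probabilities; column 2 is the
#'   seizure-class score used for ROC analysis.
#' @export
predictScores <- function(model, seqs) {
  stopifnot(is(model, "TrainedModel"))
  seqs <- .asSequenceList(seqs)
  out <- matrix(0, length(seqs), model@config@nClasses)
  for (i in seq_along(seqs)) {
    z <- ltyForward(seqs[[i]] / model@inputScale, model@config, model@weights)
    p <- exp(z - max(z))
    out[i, ] <- p / sum(p)
  }
  out
}
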