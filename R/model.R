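#' Uniform quantization to an n-bit grid
#'
#' Fake (simulated) quantization: `Q(x) = delta * floor(x / delta + 1/2)`
#' with step `delta = 2 * max(|x|) / 2^n` determined from the tensor itself.
#' The all-zero tensor is handled by defining `delta = 1` (so `Q` is
#' identically zero) to avoid division by zero on silent inputs.
#'
#' @param x numeric vector/matrix/array.
#' @param nBits bit width n >= 1.
#' @return list with `x` (the quantized tensor, same shape) and `spec`
#'   (list with `n`, `delta`, `maxAbs`).
#' @export
quantize <- function(x, nBits) {
  if (nBits < 1) stop("nBits must be >= 1")
  maxAbs <- max(abs(x))
  delta <- if (maxAbs == 0) 1 else 2 * maxAbs / 2^nBits
  xq <- delta * floor(x / delta + 0.5)
  list(x = xq, spec = list(n = as.integer(nBits), delta = delta,
                           maxAbs = maxAbs))
}

#' Mean absolute quantization error
#'
#' `E = E[|x - Q(x)|]`, the empirical mean absolute deviation between a
#' tensor and its n-bit quantization.
#'
#' @inheritParams quantize
#' @return scalar mean absolute error.
#' @export
quantizationError <- function(x, nBits) {
  mean(abs(x - quantize(x, nBits)$x))
}

#' Receptive field of a dilated convolution
#'
#' `R = k + (k - 1) (d - 1)`: the span of input positions a single output
#' position depends on. At `d = 1` this collapses to the kernel size.
#'
#' @param k kernel size >= 1.
#' @param d dilation rate >= 1.
#' @return integer receptive field.
#' @export
receptiveField <- function(k, d) {
  stopifnot(k >= 1, d >= 1)
  as.integer(k + (k - 1) * (d - 1))
}

# im2col over the time axis with "same" zero padding and dilation.
# X is T x C; returns T x (k*C) with tap-major column blocks.
.im2col <- function(X, k, d) {
  T <- nrow(X); C <- ncol(X)
  center <- (k - 1) %/% 2
  Xpad <- rbind(X, 0)
  cols <- vector("list", k)
  for (m in seq_len(k)) {
    idx <- seq_len(T) + d * (m - 1 - center)
    idx[idx < 1 | idx > T] <- T + 1L
    cols[[m]] <- Xpad[idx, , drop = FALSE]
  }
  do.call(cbind, cols)
}

# backward of .im2col: scatter dC (T x k*C) back to dX (T x C)
.col2im <- function(dC, T, C, k, d) {
  center <- (k - 1) %/% 2
  dXpad <- matrix(0, T + 1, C)
  for (m in seq_len(k)) {
    idx <- seq_len(T) + d * (m - 1 - center)
    idx[idx < 1 | idx > T] <- T + 1L
    dXpad[idx, ] <- dXpad[idx, ] + dC[, (m - 1) * C + seq_len(C), drop = FALSE]
  }
  dXpad[seq_len(T), , drop = FALSE]
}

# [C_out x C_in x k] kernel array -> (k*C_in) x C_out matrix matching .im2col
.kernelToMatrix <- function(W) {
  d <- dim(W); Cout <- d[1]; Cin <- d[2]; k <- d[3]
  M <- matrix(0, k * Cin, Cout)
  for (m in seq_len(k))
    M[(m - 1) * Cin + seq_len(Cin), ] <- t(matrix(W[, , m], Cout, Cin))
  M
}

#' 1-D dilated convolution over the time axis
#'
#' Output position t of channel j sums `A(t + d m) W(m)` over kernel taps m
#' and input channels, with taps spaced `d` samples apart and symmetric
#' "same" zero padding so the sequence length is preserved. At `d = 1` this
#' is exactly a standard convolution (cross-correlation form).
#'
#' @param seq C_in x T numeric matrix.
#' @param weights C_out x C_in x k numeric array.
#' @param d dilation rate >= 1.
#' @param bias optional length-C_out bias (default zeros).
#' @return C_out x T matrix.
#' @export
dilatedConv <- function(seq, weights, d = 1, bias = NULL) {
  stopifnot(length(dim(weights)) == 3, d >= 1)
  k <- dim(weights)[3]
  T <- ncol(seq)
  if (receptiveField(k, d) > T)
    stop("effective receptive field ", receptiveField(k, d),
         " exceeds sequence length ", T)
  if (dim(weights)[2] != nrow(seq))
    stop("weight input channels must match seq channels")
  if (is.null(bias)) bias <- rep(0, dim(weights)[1])
  M <- .kernelToMatrix(weights)
  out <- .im2col(t(seq), k, d) %*% M
  t(sweep(out, 2, bias, "+"))
}

#' Dilated convolution with quantized activations and weights
#'
#' `O_q = Q(A) * Q(W)` with taps spaced by the dilation rate: both the input
#' activations and the kernel are quantized to `nBits` before the dilated
#' convolution. Quantization is simulated in floating point; as `nBits`
#' grows the output converges to the full-precision dilated convolution.
#'
#' @inheritParams dilatedConv
#' @param nBits quantization bit width.
#' @return C_out x T matrix.
#' @export
quantizedDilatedConv <- function(seq, weights, d = 1, nBits = 8, bias = NULL) {
  qa <- quantize(seq, nBits)
  qw <- quantize(weights, nBits)
  dilatedConv(qa$x, qw$x, d = d, bias = bias)
}

#' Construct an LTY-CNN configuration
#'
#' Defaults instantiate the reference architecture: a 64-dim, 127-step
#' input; three parallel branches with kernels 7/5/3 and 4 channels each;
#' an 8-bit quantized dilated convolution (kernel 3, dilation 2) projecting
#' the 12 concatenated branch channels to the 64-dim attention width; layer
#' normalization; 4-head self-attention at total width 64 (16 dims per
#' head); mean pooling over time; and a 2-class linear head. The reference
#' instantiation has 23118 trainable parameters, within the 24506 budget.
#'
#' @param inputDim,seqLen,branchKernels,branchChannels,qBits,dilation,dilatedKernel,dilatedOut,attnHeads,attnDim,nClasses,parameterBudget see [ModelConfig-class].
#' @return a validated [ModelConfig-class].
#' @export
modelConfig <- function(inputDim = 64, seqLen = 127,
                        branchKernels = c(7, 5, 3),
                        branchChannels = c(4, 4, 4),
                        qBits = 8, dilation = 2, dilatedKernel = 3,
                        dilatedOut = 64, attnHeads = 4, attnDim = 64,
                        nClasses = 2, parameterBudget = 24506) {
  new("ModelConfig", inputDim = as.integer(inputDim),
      seqLen = as.integer(seqLen),
      branchKernels = as.integer(branchKernels),
      branchChannels = as.integer(branchChannels),
      qBits = as.integer(qBits), dilation = as.integer(dilation),
      dilatedKernel = as.integer(dilatedKernel),
      dilatedOut = as.integer(dilatedOut),
      attnHeads = as.integer(attnHeads), attnDim = as.integer(attnDim),
      nClasses = as.integer(nClasses),
      parameterBudget = as.integer(parameterBudget))
}

#' Count trainable parameters of a configuration
#'
#' Closed-form per-layer sums: each branch contributes
#' `inputDim * k * C + C`; the dilated layer `sum(C) * k_d * out + out`;
#' layer normalization `2 * out`; attention `3 (D^2 + D)` in-projections
#' plus `D^2 + D` out-projection; the classifier `D * nClasses + nClasses`.
#' [enumerateParameters()] must agree by brute force.
#'
#' @param config a [ModelConfig-class].
#' @return integer parameter count.
#' @export
countParameters <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  branches <- sum(config@inputDim * config@branchKernels * config@branchChannels +
                  config@branchChannels)
  cin <- sum(config@branchChannels)
  dilated <- cin * config@dilatedKernel * config@dilatedOut + config@dilatedOut
  ln <- 2L * config@dilatedOut
  D <- config@attnDim
  attn <- 3L * (D * D + D) + (D * D + D)
  cls <- D * config@nClasses + config@nClasses
  as.integer(branches + dilated + ln + attn + cls)
}

#' Brute-force parameter enumeration of an instantiated weight set
#'
#' Sums the number of scalars over every trainable tensor in a weight list
#' (as produced by [initWeights()]), independently of the closed-form
#' accounting of [countParameters()].
#'
#' @param weights nested list of numeric tensors.
#' @return integer total number of scalars.
#' @export
enumerateParameters <- function(weights) {
  total <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) total <<- total + length(x)
    invisible(NULL)
  }
  walk(weights)
  total
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize LTY-CNN weights
#'
#' Glorot-uniform weight matrices, zero biases, unit layer-norm gain.
#' Convolution kernels are stored as `(k * C_in) x C_out` matrices whose row
#' blocks are kernel taps (matching the internal im2col layout).
#'
#' @param config a [ModelConfig-class].
#' @param seed integer RNG seed.
#' @return nested weight list with entries `branches`, `dilated`, `ln`,
#'   `attn`, `out`.
#' @export
initWeights <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  set.seed(seed)
  D <- config@inputDim
  branches <- lapply(seq_along(config@branchKernels), function(j) {
    k <- config@branchKernels[j]; C <- config@branchChannels[j]
    list(W = .glorot(D * k, C), b = rep(0, C))
  })
  cin <- sum(config@branchChannels)
  dilated <- list(W = .glorot(cin * config@dilatedKernel, config@dilatedOut),
                  b = rep(0, config@dilatedOut))
  ln <- list(gamma = rep(1, config@dilatedOut), beta = rep(0, config@dilatedOut))
  A <- config@attnDim
  attn <- list(Wq = .glorot(A, A), bq = rep(0, A),
               Wk = .glorot(A, A), bk = rep(0, A),
               Wv = .glorot(A, A), bv = rep(0, A),
               Wo = .glorot(A, A), bo = rep(0, A))
  out <- list(W = .glorot(A, config@nClasses), b = rep(0, config@nClasses))
  list(branches = branches, dilated = dilated, ln = ln, attn = attn, out = out)
}

.softmaxRows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Concatenated parallel convolution branches
#'
#' Applies the three (in general, all configured) 1-D convolution branches
#' with different kernel sizes to the same input, passes each through the
#' ReLU activation, and concatenates the branch outputs along the channel
#' axis: `F_total = Concat[Act(F_wide), Act(F_medium), Act(F_narrow)]`.
#' Each branch depends only on the shared input, so the branch computations
#' are order-independent.
#'
#' @param seq inputDim x T matrix.
#' @param config a [ModelConfig-class].
#' @param weights weight list as from [initWeights()] (the `branches` part
#'   is used).
#' @return `sum(branchChannels)` x T matrix.
#' @export
parallelBranches <- function(seq, config, weights) {
  stopifnot(is(config, "ModelConfig"), nrow(seq) == config@inputDim)
  T <- ncol(seq)
  if (any(config@branchKernels > T))
    stop("branch kernel exceeds sequence length ", T)
  X <- t(seq)
  outs <- lapply(seq_along(config@branchKernels), function(j) {
    k <- config@branchKernels[j]
    Z <- .im2col(X, k, 1L) %*% weights$branches[[j]]$W
    Z <- sweep(Z, 2, weights$branches[[j]]$b, "+")
    pmax(Z, 0)
  })
  t(do.call(cbind, outs))
}

#' Multihead scaled dot-product self-attention
#'
#' Self-attention over the time axis: the input is projected to queries,
#' keys and values; each of the N heads attends with
#' `softmax(Q K^T / sqrt(d_k)) V` on its own `d_k = attnDim / N` slice; head
#' outputs are concatenated and projected by `W^O`. Every attention row is
#' a probability vector (nonnegative, summing to 1).
#'
#' @param seq T x attnDim matrix.
#' @param params attention weight list (`Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`,
#'   `Wo`, `bo`), e.g. the `attn` entry of [initWeights()].
#' @param nHeads number of heads (default 4).
#' @param returnWeights if TRUE, also return the per-head T x T attention
#'   matrices.
#' @return T x attnDim output matrix, or a list with `output` and
#'   `attention` when `returnWeights` is TRUE.
#' @export
multiheadAttention <- function(seq, params, nHeads = 4, returnWeights = FALSE) {
  D <- ncol(seq)
  if (D %% nHeads != 0) stop("attention width must be divisible by the head count")
  dk <- D %/% nHeads
  Q <- sweep(seq %*% params$Wq, 2, params$bq, "+")
  K <- sweep(seq %*% params$Wk, 2, params$bk, "+")
  V <- sweep(seq %*% params$Wv, 2, params$bv, "+")
  O <- matrix(0, nrow(seq), D)
  attw <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    idx <- (h - 1) * dk + seq_len(dk)
    P <- .softmaxRows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk))
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    if (returnWeights) attw[[h]] <- P
  }
  out <- sweep(O %*% params$Wo, 2, params$bo, "+")
  if (returnWeights) list(output = out, attention = attw) else out
}

# full forward pass with cached intermediates for backprop.
# X is seqLen x inputDim (one window's feature sequence, already scaled).
.forwardCache <- function(X, config, w) {
  T <- nrow(X)
  nb <- length(config@branchKernels)
  Cs <- vector("list", nb); Hs <- vector("list", nb); masks <- vector("list", nb)
  for (j in seq_len(nb)) {
    k <- config@branchKernels[j]
    Cs[[j]] <- .im2col(X, k, 1L)
    Z <- sweep(Cs[[j]] %*% w$branches[[j]]$W, 2, w$branches[[j]]$b, "+")
    masks[[j]] <- Z > 0
    Hs[[j]] <- pmax(Z, 0)
  }
  H1 <- do.call(cbind, Hs)                      # T x sum(C)

  qa <- quantize(H1, config@qBits)
  qw <- quantize(w$dilated$W, config@qBits)
  C2 <- .im2col(qa$x, config@dilatedKernel, config@dilation)
  Z2 <- sweep(C2 %*% qw$x, 2, w$dilated$b, "+") # T x dilatedOut

  mu <- rowMeans(Z2)
  xc <- Z2 - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + 1e-5)
  Xn <- xc * inv
  H3 <- sweep(sweep(Xn, 2, w$ln$gamma, "*"), 2, w$ln$beta, "+")

  D <- config@attnDim
  nH <- config@attnHeads
  dk <- D %/% nH
  Q <- sweep(H3 %*% w$attn$Wq, 2, w$attn$bq, "+")
  K <- sweep(H3 %*% w$attn$Wk, 2, w$attn$bk, "+")
  V <- sweep(H3 %*% w$attn$Wv, 2, w$attn$bv, "+")
  O <- matrix(0, T, D)
  Ps <- vector("list", nH)
  for (h in seq_len(nH)) {
    idx <- (h - 1) * dk + seq_len(dk)
    Ps[[h]] <- .softmaxRows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk))
    O[, idx] <- Ps[[h]] %*% V[, idx, drop = FALSE]
  }
  A <- sweep(O %*% w$attn$Wo, 2, w$attn$bo, "+")

  pooled <- colMeans(A)
  logits <- drop(pooled %*% w$out$W) + w$out$b

  list(X = X, Cs = Cs, masks = masks, H1 = H1, C2 = C2, qw = qw,
       Xn = Xn, inv = inv, H3 = H3, Q = Q, K = K, V = V, Ps = Ps, O = O,
       A = A, pooled = pooled, logits = logits, T = T, dk = dk)
}

# backward pass; dlogits is the gradient at the logits. Returns the nested
# gradient list (same shape as weights). Straight-through estimator: the
# quantizers in the dilated layer pass gradients through unchanged.
.backward <- function(cache, config, w, dlogits) {
  g <- list()
  T <- cache$T
  g$out <- list(W = outer(cache$pooled, dlogits), b = dlogits)
  dpooled <- drop(w$out$W %*% dlogits)
  dA <- matrix(dpooled / T, T, length(dpooled), byrow = TRUE)

  g$attn <- list()
  g$attn$bo <- colSums(dA)
  g$attn$Wo <- crossprod(cache$O, dA)
  dO <- dA %*% t(w$attn$Wo)
  D <- config@attnDim; nH <- config@attnHeads; dk <- cache$dk
  dQ <- matrix(0, T, D); dK <- matrix(0, T, D); dV <- matrix(0, T, D)
  for (h in seq_len(nH)) {
    idx <- (h - 1) * dk + seq_len(dk)
    P <- cache$Ps[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dP <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  g$attn$Wq <- crossprod(cache$H3, dQ); g$attn$bq <- colSums(dQ)
  g$attn$Wk <- crossprod(cache$H3, dK); g$attn$bk <- colSums(dK)
  g$attn$Wv <- crossprod(cache$H3, dV); g$attn$bv <- colSums(dV)
  dH3 <- dQ %*% t(w$attn$Wq) + dK %*% t(w$attn$Wk) + dV %*% t(w$attn$Wv)

  g$ln <- list(gamma = colSums(dH3 * cache$Xn), beta = colSums(dH3))
  dXn <- sweep(dH3, 2, w$ln$gamma, "*")
  # layer-norm backward, normalizing over the feature axis per time step
  dZ2 <- cache$inv * (dXn - rowMeans(dXn) - cache$Xn * rowMeans(dXn * cache$Xn))

  g$dilated <- list(W = crossprod(cache$C2, dZ2), b = colSums(dZ2))
  dC2 <- dZ2 %*% t(cache$qw$x)
  dH1 <- .col2im(dC2, T, ncol(cache$H1), config@dilatedKernel, config@dilation)

  g$branches <- vector("list", length(config@branchKernels))
  off <- 0
  for (j in seq_along(config@branchKernels)) {
    C <- config@branchChannels[j]
    dHj <- dH1[, off + seq_len(C), drop = FALSE] * cache$masks[[j]]
    g$branches[[j]] <- list(W = crossprod(cache$Cs[[j]], dHj), b = colSums(dHj))
    off <- off + C
  }
  # same structure and ordering as the weight list (positional updates)
  list(branches = g$branches, dilated = g$dilated,
       ln = list(gamma = g$ln$gamma, beta = g$ln$beta),
       attn = g$attn[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")],
       out = g$out)
}

#' LTY-CNN forward pass
#'
#' Full pipeline for one feature sequence: parallel convolution branches
#' with ReLU, quantization-aware dilated convolution to the attention width,
#' layer normalization, multihead self-attention over the time axis, mean
#' pooling over time, and the linear classifier. Deterministic given weights
#' and input.
#'
#' @param seq seqLen x inputDim matrix (one window's feature sequence).
#' @param config a [ModelConfig-class].
#' @param weights weight list from [initWeights()] or a trained model.
#' @return numeric vector of `nClasses` unnormalized class scores (logits).
#' @export
ltyForward <- function(seq, config, weights) {
  seq <- as.matrix(seq)
  if (ncol(seq) != config@inputDim)
    stop("input stage: sequence feature dimension ", ncol(seq),
         " does not match inputDim ", config@inputDim)
  .forwardCache(seq, config, weights)$logits
}
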