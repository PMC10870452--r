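test_that("quantization follows the printed step and rounding rules", {
  # max|x| = 2, n = 2 -> delta = 1; Q(0.75) = 1; Q(0) = 0
  q <- quantize(c(0.75, 0, -2, 2), 2)
  expect_equal(q$spec$delta, 1)
  expect_equal(q$x, c(1, 0, -2, 2))
  expect_error(quantize(1:3, 0), "nBits")
  # zero-safe: silent input stays silent
  q0 <- quantize(rep(0, 5), 8)
  expect_true(all(q0$x == 0))
})

test_that("quantization satisfies its bound, idempotence and level-count laws", {
  set.seed(11)
  for (n in c(2, 4, 8)) {
    x <- rnorm(500, sd = 3)
    q <- quantize(x, n)
    expect_lte(max(abs(x - q$x)), q$spec$delta / 2 + 1e-12)
    expect_equal(quantize(q$x, n)$x, q$x)           # idempotent
    expect_lte(length(unique(q$x)), 2^n + 1)        # level count
  }
})

test_that("quantization error matches the uniform-density expectation and shrinks with bit width", {
  set.seed(12)
  # x on the grid -> zero error
  g <- quantize(rnorm(100), 4)
  expect_equal(quantizationError(g$x, 4), 0)
  # uniform input: E[|x - Q(x)|] ~ delta / 4 (Monte-Carlo oracle)
  x <- runif(2e5, -1, 1)
  delta <- 2 * max(abs(x)) / 2^6
  expect_equal(quantizationError(x, 6), delta / 4, tolerance = 0.02)
  # nonincreasing in n on one fixed vector
  xf <- rnorm(1000)
  errs <- vapply(c(2, 4, 8), function(n) quantizationError(xf, n), 0)
  expect_true(all(diff(errs) <= 0))
})

test_that("the receptive-field formula matches its printed values and collapses at d = 1", {
  expect_equal(receptiveField(3, 1), 3L)
  expect_equal(receptiveField(3, 2), 5L)
  expect_equal(receptiveField(5, 3), 13L)
  for (k in c(1, 3, 5, 9)) expect_equal(receptiveField(k, 1), as.integer(k))
})

test_that("dilated convolution at d = 1 equals a direct standard-convolution oracle", {
  set.seed(13)
  for (i in 1:20) {
    Cin <- sample(1:4, 1); Cout <- sample(1:4, 1)
    k <- sample(c(1, 3, 5), 1); T <- sample(10:20, 1)
    A <- matrix(rnorm(Cin * T), Cin, T)
    W <- array(rnorm(Cout * Cin * k), dim = c(Cout, Cin, k))
    expect_equal(dilatedConv(A, W, d = 1), naiveDilatedConv(A, W, 1),
                 tolerance = 1e-6)
  }
})

test_that("dilated convolution matches the naive oracle at d > 1 and has the right impulse support", {
  set.seed(14)
  A <- matrix(rnorm(3 * 30), 3, 30)
  W <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
  expect_equal(dilatedConv(A, W, d = 2), naiveDilatedConv(A, W, 2),
               tolerance = 1e-12)
  # impulse at position 15, k = 3, d = 2 -> support exactly {-2, 0, +2}
  imp <- matrix(0, 1, 30); imp[1, 15] <- 1
  Wones <- array(1, dim = c(1, 1, 3))
  out <- dilatedConv(imp, Wones, d = 2)
  expect_equal(which(out[1, ] != 0), c(13, 15, 17))
  # receptive field exceeding the sequence is refused
  expect_error(dilatedConv(matrix(0, 1, 4), Wones, d = 2), "receptive field")
})

test_that("quantized dilated convolution degrades gracefully and is exact on grid inputs", {
  set.seed(15)
  A <- matrix(rnorm(4 * 25), 4, 25)
  W <- array(rnorm(3 * 4 * 3), dim = c(3, 4, 3))
  full <- dilatedConv(A, W, d = 2)
  q16 <- quantizedDilatedConv(A, W, d = 2, nBits = 16)
  dA <- 2 * max(abs(A)) / 2^16
  dW <- 2 * max(abs(W)) / 2^16
  # |Q(A)Q(W) - AW| <= dA/2 * sum|Q(W)| + dW/2 * sum|A| per output entry
  qW <- quantize(W, 16)$x
  bound <- dA / 2 * sum(abs(qW)) + dW / 2 * 3 * 4 * max(abs(A))
  expect_lte(max(abs(q16 - full)), bound)
  # zero weights -> zero output at any bit width
  expect_true(all(quantizedDilatedConv(A, 0 * W, d = 2, nBits = 2) == 0))
  # inputs and weights already on the n-bit grid -> exact equality
  Ag <- quantize(A, 6)$x; Wg <- quantize(W, 6)$x
  expect_equal(quantizedDilatedConv(Ag, Wg, d = 2, nBits = 6),
               dilatedConv(Ag, Wg, d = 2), tolerance = 1e-12)
})

test_that("parallel branches concatenate activated outputs along the channel axis", {
  cfg <- modelConfig()
  w <- initWeights(cfg, seed = 2)
  set.seed(16)
  x <- matrix(rnorm(64 * 127), 64, 127)
  out <- parallelBranches(x, cfg, w)
  expect_equal(dim(out), c(12, 127))
  expect_true(all(out >= 0))                      # ReLU output
  # zero input and zero biases -> zero output
  expect_true(all(parallelBranches(matrix(0, 64, 127), cfg, w) == 0))
  # permuting branch order permutes the channel blocks, values unchanged
  cfgP <- modelConfig(branchKernels = c(3, 5, 7))
  wP <- w; wP$branches <- w$branches[c(3, 2, 1)]
  outP <- parallelBranches(x, cfgP, wP)
  expect_equal(outP, out[c(9:12, 5:8, 1:4), ])
})

test_that("multihead attention rows are probability vectors with the printed degenerate cases", {
  cfg <- modelConfig()
  w <- initWeights(cfg, seed = 3)
  set.seed(17)
  x <- matrix(rnorm(127 * 64), 127, 64)
  res <- multiheadAttention(x, w$attn, nHeads = 4, returnWeights = TRUE)
  for (P in res$attention) {
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, 127), tolerance = 1e-6)
  }
  # sequence length 1: the softmax is the scalar 1 and output is V W^O + b
  x1 <- matrix(rnorm(64), 1, 64)
  V1 <- sweep(x1 %*% w$attn$Wv, 2, w$attn$bv, "+")
  expect_equal(multiheadAttention(x1, w$attn, 4),
               sweep(V1 %*% w$attn$Wo, 2, w$attn$bo, "+"), tolerance = 1e-12)
  # identical keys -> uniform attention -> every output row identical
  wEq <- w$attn; wEq$Wk <- 0 * wEq$Wk
  outEq <- multiheadAttention(x, wEq, 4, returnWeights = TRUE)
  expect_equal(max(abs(outEq$attention[[1]] - 1 / 127)), 0, tolerance = 1e-12)
  expect_lt(max(abs(sweep(outEq$output, 2, outEq$output[1, ]))), 1e-9)
  expect_error(multiheadAttention(x, w$attn, nHeads = 5), "divisible")
})

test_that("attention output is invariant to permuting heads with their W^O blocks", {
  cfg <- modelConfig()
  w <- initWeights(cfg, seed = 5)
  set.seed(19)
  x <- matrix(rnorm(127 * 64), 127, 64)
  base <- multiheadAttention(x, w$attn, 4)
  # swap heads (1,2,3,4) -> (3,4,1,2): permute the 16-column slices of the
  # in-projections and the matching 16-row blocks of W^O
  colperm <- c(33:64, 1:32)
  wp <- w$attn
  for (nm in c("Wq", "Wk", "Wv")) wp[[nm]] <- wp[[nm]][, colperm]
  for (nm in c("bq", "bk", "bv")) wp[[nm]] <- wp[[nm]][colperm]
  wp$Wo <- wp$Wo[colperm, ]
  expect_equal(multiheadAttention(x, wp, 4), base, tolerance = 1e-12)
})

test_that("parameter accounting: closed form, brute force and the printed budget agree", {
  cfg <- modelConfig()
  expect_equal(countParameters(cfg), 23118L)
  expect_lte(countParameters(cfg), 24506L)
  w <- initWeights(cfg, 1)
  expect_equal(enumerateParameters(w), countParameters(cfg))
  # instantiated sub-blocks: linear 64 -> 2 head has 130 scalars,
  # the 64-dim attention block 16640
  expect_equal(enumerateParameters(w$out), 130L)
  expect_equal(enumerateParameters(w$attn), 16640L)
  # accounting also agrees on non-reference shapes
  alt <- modelConfig(branchKernels = c(9, 5, 3), branchChannels = c(2, 4, 6))
  expect_equal(enumerateParameters(initWeights(alt, 2)), countParameters(alt))
  # a config violating the budget is rejected by the validity method
  expect_error(modelConfig(branchChannels = c(16, 16, 16), parameterBudget = 24506),
               "budget")
})

test_that("the forward pass is deterministic, two-class, and sensitive to time order", {
  cfg <- modelConfig()
  w <- initWeights(cfg, seed = 4)
  set.seed(18)
  x <- matrix(rnorm(127 * 64), 127, 64)
  z1 <- ltyForward(x, cfg, w)
  expect_length(z1, 2)
  expect_identical(z1, ltyForward(x, cfg, w))
  p <- exp(z1 - max(z1)); p <- p / sum(p)
  expect_equal(sum(p), 1)
  # shuffling time frames changes the scores for generic weights
  xs <- x[sample(127), ]
  expect_gt(max(abs(ltyForward(xs, cfg, w) - z1)), 1e-8)
  expect_error(ltyForward(matrix(0, 127, 32), cfg, w), "inputDim")
})
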