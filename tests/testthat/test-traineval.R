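test_that("confusion counts and ratios follow the printed formulas", {
  truth <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(1, 50), rep(1, 10), rep(0, 40))  # TP 50, FP 10, TN 40, FN 0
  m <- computeMetrics(pred, truth)
  expect_equal(m[c("TP", "TN", "FP", "FN")], list(TP = 50L, TN = 40L,
                                                  FP = 10L, FN = 0L))
  expect_equal(m$acc, 0.9)
  expect_equal(m$sen, 1.0)
  expect_equal(m$spe, 0.8)
  perfect <- computeMetrics(truth, truth)
  expect_equal(c(perfect$acc, perfect$sen, perfect$spe), c(1, 1, 1))
  expect_error(computeMetrics(c(0, 1), c(0, 1, 1)), "length")
})

test_that("undefined ratios are flagged, never silently zero", {
  m <- computeMetrics(c(0, 0, 1), c(0, 0, 0))  # no positive truths
  expect_true(is.nan(m$sen))
  expect_false(m$senDefined)
  m2 <- computeMetrics(c(1, 0), c(1, 1))       # no negative truths
  expect_true(is.nan(m2$spe))
  expect_false(m2$speDefined)
})

test_that("metric identities hold on random instances", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    m <- computeMetrics(pred, truth)
    tpr <- m$TP / (m$TP + m$FN)
    fpr <- m$FP / (m$FP + m$TN)
    expect_equal(m$sen, tpr)                       # Sen == TPR
    expect_equal(1 - m$spe, fpr)                   # FPR == 1 - Spe
    prev <- mean(truth)
    expect_equal(m$acc, prev * m$sen + (1 - prev) * m$spe)  # convexity
  }
})

test_that("trapezoidal AUC matches its printed examples and tie convention", {
  expect_equal(rocAuc(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1))$auc, 1.0)
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(rocAuc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  r <- rocAuc(rnorm(20), rep(0:1, 10))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("trapezoidal AUC equals brute-force pairwise concordance", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(rocAuc(scores, labels)$auc, aucByPairs(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  labels <- rep(c(0, 1), c(90, 10))
  folds <- kfoldSplit(labels, k = 5, seed = 2)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 20))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    npos <- sum(labels[f$test] == 1)
    expect_true(abs(npos - 2) <= 1)   # 10% positives -> 2 per fold +/- 1
  }
  expect_error(kfoldSplit(labels, k = 101), "exceeds")
})

test_that("group-aware splitting keeps each recording in one fold", {
  labels <- rbinom(40, 1, 0.5)
  groups <- rep(paste0("rec", 1:8), each = 5)
  folds <- kfoldSplit(labels, k = 4, seed = 3, groups = groups)
  for (f in folds) {
    gTest <- unique(groups[f$test])
    gTrain <- unique(groups[f$train])
    expect_length(intersect(gTest, gTrain), 0)
  }
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:40)
})

test_that("training is reproducible, inert at zero learning rate, and needs both classes", {
  set.seed(23)
  seqs <- lapply(1:8, function(i) matrix(rnorm(20 * 8), 20, 8))
  labs <- rep(0:1, 4)
  cfg <- modelConfig(inputDim = 8, seqLen = 20, branchKernels = c(5, 3, 3),
                     branchChannels = c(2, 2, 2), dilatedOut = 8,
                     attnHeads = 2, attnDim = 8)
  tc0 <- trainConfig(epochs = 2, learningRate = 0, seed = 5)
  m0 <- trainModel(seqs, labs, cfg, tc0)
  expect_equal(m0@weights, initWeights(cfg, seed = 5L))
  tc <- trainConfig(epochs = 3, seed = 6)
  mA <- trainModel(seqs, labs, cfg, tc)
  mB <- trainModel(seqs, labs, cfg, tc)
  expect_identical(mA@lossCurve, mB@lossCurve)
  expect_length(mA@lossCurve, 3)
  expect_error(trainModel(seqs, rep(1L, 8), cfg, tc), "both classes")
})

test_that("training loss decreases over the first epochs on a strongly separable task", {
  cfg <- modelConfig(inputDim = 8, seqLen = 32, branchKernels = c(5, 3, 3),
                     branchChannels = c(2, 2, 2), dilatedOut = 8,
                     attnHeads = 2, attnDim = 8)
  decreasing <- 0
  for (seed in 1:5) {
    set.seed(100 + seed)
    labs <- rep(0:1, each = 12)
    seqs <- lapply(labs, function(y) {
      s <- matrix(rnorm(32 * 8), 32, 8)
      if (y == 1) s[, 2] <- s[, 2] + 3   # strong class effect
      s
    })
    m <- trainModel(seqs, labs, cfg, trainConfig(epochs = 5, seed = seed))
    if (all(diff(m@lossCurve) < 0)) decreasing <- decreasing + 1
  }
  expect_gte(decreasing, 4)
})

test_that("cross-validated evaluation reports per-fold metrics on a separable task", {
  ws <- makeTinyWindowSet(n = 30)
  cfg <- modelConfig(inputDim = 6, seqLen = 7, branchKernels = c(5, 3, 3),
                     branchChannels = c(2, 2, 2), dilatedOut = 8,
                     attnHeads = 2, attnDim = 8)
  tc <- trainConfig(epochs = 8, kFolds = 5, seed = 7)
  rep <- evaluateCV(ws, cfg, tc, pcaK = 6,
                    stft = stftConfig(nfft = 64, hop = 32, fmin = 1, fmax = 20))
  expect_equal(nrow(rep$perFold), 5)
  expect_equal(sum(rep$perFold$n), 30)
  expect_true(all(rep$perFold$TP + rep$perFold$TN + rep$perFold$FP +
                  rep$perFold$FN == rep$perFold$n))
  expect_gt(rep$mean["auc"], 0.9)   # 5 Hz rhythm is easy to separate
  expect_length(rep$lossCurves, 5)
  # grouped splitting: no test window shares a recording with training
  tcg <- trainConfig(epochs = 2, kFolds = 2, seed = 8)
  repg <- evaluateCV(ws, cfg, tcg, pcaK = 6, groupByRecording = TRUE,
                     stft = stftConfig(nfft = 64, hop = 32, fmin = 1, fmax = 20))
  src <- windowSources(ws)
  for (f in repg$foldAssignment)
    expect_length(intersect(unique(src[f$test]), unique(src[f$train])), 0)
})
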