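#' Build the packaged synthetic seizure dataset
#'
#' Simulates a set of independent 18-channel recordings, preprocesses each
#' (powerline band-stop and 1 Hz high-pass; the simulator already emits
#' 256 Hz), cuts non-overlapping 64-s windows, labels them against the
#' seizure annotations, balances the classes by overlapped sampling of the
#' seizure spans, and concatenates everything into one labelled window set.
#'
#' @param nRecordings number of simulated recordings (default 10).
#' @param seed base RNG seed; recording r uses `seed + r`.
#' @param ... overrides passed to [synthConfig()] for every recording.
#' @return a labelled, class-balanced [EEGWindowSet-class].
#' @export
syntheticSeizureWindows <- function(nRecordings = 10, seed = 1L, ...) {
  sets <- vector("list", nRecordings)
  for (r in seq_len(nRecordings)) {
    cfg <- synthConfig(seed = seed + r, ...)
    rec <- simulateRecording(cfg)
    rec <- applyHighpass(applyBandstop(rec))
    ws <- segmentWindows(rec, windowS = 64, strideS = 64)
    ws <- labelWindows(ws, annotations(rec))
    sets[[r]] <- balanceByOverlap(ws, rec, minorityStrideS = 16,
                                  targetRatio = 1)
  }
  combineWindowSets(sets)
}

#' Spectrogram frames and PCA features for a window set
#'
#' Computes per-window spectrograms, optionally fits a PCA basis on (a
#' subsample of) the frames, and projects every window into its
#' seqLen x k feature sequence.
#'
#' @param ws an [EEGWindowSet-class].
#' @param basis an existing [PCABasis-class], or NULL to fit one here.
#' @param k number of components when fitting (default 64).
#' @param maxFrames cap on the number of frames used to fit the basis
#'   (default 3000; frames are subsampled with `seed`).
#' @param seed RNG seed for the frame subsample.
#' @param stft an [stftConfig()].
#' @return list with `seqs` (list of sequences) and `basis`.
#' @export
featurizeWindowSet <- function(ws, basis = NULL, k = 64, maxFrames = 3000,
                               seed = 1L, stft = stftConfig()) {
  stopifnot(is(ws, "EEGWindowSet"))
  frameList <- lapply(seq_len(nWindows(ws)), function(i)
    spectrogramFrames(computeSpectrogram(getWindow(ws, i), fs = ws@fs,
                                         stft = stft)))
  if (is.null(basis)) {
    frames <- do.call(rbind, frameList)
    if (nrow(frames) > maxFrames) {
      set.seed(seed)
      frames <- frames[sample.int(nrow(frames), maxFrames), , drop = FALSE]
    }
    basis <- fitPCA(frames, k = k)
  }
  list(seqs = lapply(frameList, applyPCA, basis = basis), basis = basis)
}

#' Cross-validated training and evaluation
#'
#' The full protocol: per-window spectrograms are computed once; the data
#' are split into k folds (stratified by default, optionally grouped by
#' source recording so no recording contributes to both sides); within each
#' fold a PCA basis is fitted on training frames only, both splits are
#' projected, the classifier is trained on the training split and evaluated
#' on the held-out split. Accuracy, sensitivity, specificity, the ROC curve
#' and AUC are reported per fold and as means.
#'
#' @param ws a labelled [EEGWindowSet-class].
#' @param config a [ModelConfig-class].
#' @param tconfig a [trainConfig()]; `kFolds` and `seed` govern the split.
#' @param labels labels to use (default the window set's own; supply a
#'   permutation for a label-shuffle null check).
#' @param groupByRecording keep all windows of a recording in one fold.
#' @param pcaK number of principal components (default 64).
#' @param maxPcaFrames cap on frames used per-fold to fit the PCA basis.
#' @param stft an [stftConfig()].
#' @return list of class `ltyEvalReport`: `perFold` data.frame (confusion
#'   counts, acc/sen/spe, auc), `mean` (named vector), `rocs`,
#'   `lossCurves`, `explainedVariance` (cumulative at `pcaK`, per fold)
#'   and `foldAssignment`.
#' @export
evaluateCV <- function(ws, config = modelConfig(), tconfig = trainConfig(),
                       labels = windowLabels(ws), groupByRecording = FALSE,
                       pcaK = 64, maxPcaFrames = 3000, stft = stftConfig()) {
  stopifnot(is(ws, "EEGWindowSet"))
  labels <- as.integer(labels)
  frameList <- lapply(seq_len(nWindows(ws)), function(i)
    spectrogramFrames(computeSpectrogram(getWindow(ws, i), fs = ws@fs,
                                         stft = stft)))
  folds <- kfoldSplit(labels, k = tconfig$kFolds, seed = tconfig$seed,
                      stratified = tconfig$stratified,
                      groups = if (groupByRecording) windowSources(ws))
  perFold <- vector("list", length(folds))
  rocs <- vector("list", length(folds))
  lossCurves <- vector("list", length(folds))
  evRatio <- numeric(length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    frames <- do.call(rbind, frameList[tr])
    if (nrow(frames) > maxPcaFrames) {
      set.seed(tconfig$seed + f)
      frames <- frames[sample.int(nrow(frames), maxPcaFrames), , drop = FALSE]
    }
    basis <- fitPCA(frames, k = pcaK)
    evRatio[f] <- sum(explainedVariance(basis))
    trainSeqs <- lapply(frameList[tr], applyPCA, basis = basis)
    testSeqs <- lapply(frameList[te], applyPCA, basis = basis)
    model <- trainModel(trainSeqs, labels[tr], config, tconfig)
    prob <- predictScores(model, testSeqs)
    pred <- as.integer(prob[, 2] > 0.5)
    met <- computeMetrics(pred, labels[te])
    roc <- rocAuc(prob[, 2], labels[te])
    perFold[[f]] <- data.frame(fold = f, n = length(te), TP = met$TP,
                               TN = met$TN, FP = met$FP, FN = met$FN,
                               acc = met$acc, sen = met$sen, spe = met$spe,
                               auc = roc$auc)
    rocs[[f]] <- roc$roc
    lossCurves[[f]] <- model@lossCurve
  }
  perFold <- do.call(rbind, perFold)
  res <- list(perFold = perFold,
              mean = c(acc = mean(perFold$acc), sen = mean(perFold$sen),
                       spe = mean(perFold$spe), auc = mean(perFold$auc)),
              rocs = rocs, lossCurves = lossCurves,
              explainedVariance = evRatio,
              foldAssignment = folds)
  class(res) <- "ltyEvalReport"
  res
}

#' @export
print.ltyEvalReport <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation over %d fold(s)\n", nrow(x$perFold)))
  print(x$perFold, row.names = FALSE, digits = 3)
  cat(sprintf("means: acc %.3f, sen %.3f, spe %.3f, auc %.3f\n",
              x$mean["acc"], x$mean["sen"], x$mean["spe"], x$mean["auc"]))
  invisible(x)
}
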