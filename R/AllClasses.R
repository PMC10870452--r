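#' @import methods
#' @importFrom stats fft rnorm runif sd var cor quantile
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG recording: a channels-by-samples
#' signal matrix in microvolts, a single sampling rate shared by all channels,
#' and seizure annotations as half-open intervals `[start, end)` in seconds.
#'
#' @slot signal numeric matrix, channels x samples, microvolts; rownames are
#'   channel names.
#' @slot fs sampling rate in Hz.
#' @slot annotations data.frame with columns `start`, `end` (seconds) and
#'   `label`; every interval satisfies `0 <= start < end <= duration`.
#' @slot subjectId character scalar identifying the source subject/recording.
#'
#' @seealso [simulateRecording()], [readRecording()], [selectChannels()]
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    annotations = "data.frame",
    subjectId = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (is.null(rownames(object@signal)))
    msg <- c(msg, "signal must have channel names as rownames")
  ann <- object@annotations
  if (!all(c("start", "end", "label") %in% names(ann)))
    msg <- c(msg, "annotations need columns start, end, label")
  else if (nrow(ann) > 0) {
    dur <- ncol(object@signal) / object@fs
    if (any(ann$start < 0) || any(ann$end > dur + 1e-9) ||
        any(ann$start >= ann$end))
      msg <- c(msg, "every annotation must satisfy 0 <= start < end <= duration")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames character vector of channel names; defaults to existing
#'   rownames.
#' @param annotations data.frame with `start`, `end`, `label` columns
#'   (seconds, half-open intervals). Defaults to no annotations.
#' @param subjectId identifier string.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(signal, fs, channelNames = rownames(signal),
                         annotations = emptyAnnotations(),
                         subjectId = "anonymous") {
  signal <- as.matrix(signal)
  if (is.null(channelNames))
    channelNames <- paste0("CH", seq_len(nrow(signal)))
  rownames(signal) <- channelNames
  new("EEGRecording", signal = signal, fs = as.numeric(fs),
      annotations = as.data.frame(annotations), subjectId = subjectId)
}

#' @rdname EEGRecording
#' @export
emptyAnnotations <- function() {
  data.frame(start = numeric(0), end = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Set of fixed-length labelled analysis windows
#'
#' Windows cut from one or more recordings, stored as a 3-D array
#' (channels x samples x windows) with a binary label, start time and source
#' identifier per window. Labels are 0 (interictal/background) or
#' 1 (ictal/seizure).
#'
#' @slot windows numeric array, channels x window_samples x n_windows.
#' @slot labels integer vector, one of 0/1 per window.
#' @slot startS numeric vector, window start in seconds within its source.
#' @slot sourceId character vector, source recording per window.
#' @slot fs sampling rate, Hz.
#' @slot windowS window length in seconds.
#' @export
setClass("EEGWindowSet",
  representation(
    windows = "array",
    labels = "integer",
    startS = "numeric",
    sourceId = "character",
    fs = "numeric",
    windowS = "numeric"
  )
)

setValidity("EEGWindowSet", function(object) {
  msg <- character()
  d <- dim(object@windows)
  if (length(d) != 3L) msg <- c(msg, "windows must be a 3-D array")
  else {
    n <- d[3]
    if (length(object@labels) != n) msg <- c(msg, "one label per window required")
    if (length(object@startS) != n) msg <- c(msg, "one start time per window required")
    if (length(object@sourceId) != n) msg <- c(msg, "one source id per window required")
    if (d[2] != round(object@windowS * object@fs))
      msg <- c(msg, "window_samples must equal round(window_s * fs)")
  }
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Per-window time-frequency representation
#'
#' Log-magnitude short-time Fourier spectrogram of one analysis window,
#' one plane per channel. At the reference configuration (64-s window,
#' 256 Hz, 1-s Hann segments with 50% overlap, bins 1..114 Hz) each plane
#' is 127 time frames by 114 frequency bins.
#'
#' @slot values numeric array, channels x time_frames x freq_bins,
#'   `log(1 + magnitude)`.
#' @slot frameTimes frame centre times in seconds.
#' @slot binFreqs retained bin frequencies in Hz, strictly increasing.
#' @slot channelNames channel names.
#' @export
setClass("SpectrogramArray",
  representation(
    values = "array",
    frameTimes = "numeric",
    binFreqs = "numeric",
    channelNames = "character"
  )
)

setValidity("SpectrogramArray", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be channels x frames x bins")
  else {
    if (d[2] != length(object@frameTimes)) msg <- c(msg, "frameTimes length mismatch")
    if (d[3] != length(object@binFreqs)) msg <- c(msg, "binFreqs length mismatch")
    if (d[1] != length(object@channelNames)) msg <- c(msg, "channelNames length mismatch")
  }
  if (is.unsorted(object@binFreqs, strictly = TRUE))
    msg <- c(msg, "binFreqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Principal-component basis for spectrogram frames
#'
#' A basis fitted by singular value decomposition of mean-centred training
#' frames: `X = U D V^T`, with the projection `Y = X W` using the first `k`
#' right singular vectors as `W`. Carries the singular values and the total
#' variance so explained-variance ratios can be derived.
#'
#' @slot center mean vector of the training frames (length input_dim).
#' @slot rotation input_dim x k matrix with orthonormal columns.
#' @slot d first k singular values, nonincreasing.
#' @slot k number of retained components.
#' @slot totalVar total variance of the training frames (sum over all
#'   components of `d_i^2 / (n - 1)`).
#' @slot nTrain number of training frames the basis was fitted on.
#' @export
setClass("PCABasis",
  representation(
    center = "numeric",
    rotation = "matrix",
    d = "numeric",
    k = "integer",
    totalVar = "numeric",
    nTrain = "integer"
  )
)

setValidity("PCABasis", function(object) {
  msg <- character()
  if (ncol(object@rotation) != object@k) msg <- c(msg, "rotation must have k columns")
  if (nrow(object@rotation) != length(object@center))
    msg <- c(msg, "center length must match rotation rows")
  if (length(object@d) != object@k) msg <- c(msg, "d must have k entries")
  if (any(diff(object@d) > 1e-8)) msg <- c(msg, "singular values must be nonincreasing")
  if (any(object@d < -1e-12)) msg <- c(msg, "singular values must be nonnegative")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(object@k))) > 1e-8)
    msg <- c(msg, "rotation columns must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' LTY-CNN architecture configuration
#'
#' Hyperparameters of the lightweight classifier: three parallel convolution
#' branches with wide/medium/narrow kernels over the 127-step feature
#' sequence, a quantization-aware dilated convolution projecting to the
#' attention width, layer normalization, 4-head self-attention, mean pooling
#' over time and a linear 2-class head. The instantiated reference
#' configuration must stay within the published parameter budget.
#'
#' @slot inputDim feature dimension per time step (reference 64).
#' @slot seqLen sequence length in time steps (reference 127).
#' @slot branchKernels integer kernel sizes `[wide, medium, narrow]`
#'   (reference `c(7, 5, 3)`).
#' @slot branchChannels output channels per branch (reference `c(4, 4, 4)`).
#' @slot qBits quantization bit width n for the dilated layer (reference 8).
#' @slot dilation dilation rate d of the dilated convolution (reference 2).
#' @slot dilatedKernel kernel size of the dilated convolution (reference 3).
#' @slot dilatedOut output channels of the dilated convolution (reference 64,
#'   equal to the attention width).
#' @slot attnHeads number of attention heads N (reference 4).
#' @slot attnDim total attention width, split across heads (reference 64).
#' @slot nClasses number of output classes (2).
#' @slot parameterBudget maximum admissible number of trainable parameters
#'   (24506).
#' @export
setClass("ModelConfig",
  representation(
    inputDim = "integer",
    seqLen = "integer",
    branchKernels = "integer",
    branchChannels = "integer",
    qBits = "integer",
    dilation = "integer",
    dilatedKernel = "integer",
    dilatedOut = "integer",
    attnHeads = "integer",
    attnDim = "integer",
    nClasses = "integer",
    parameterBudget = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@branchKernels) != length(object@branchChannels))
    msg <- c(msg, "one channel count per branch kernel required")
  if (any(object@branchKernels < 1L)) msg <- c(msg, "branch kernels must be >= 1")
  if (any(object@branchKernels %% 2L == 0L))
    msg <- c(msg, "branch kernels must be odd for symmetric same padding")
  if (object@dilatedKernel %% 2L == 0L)
    msg <- c(msg, "dilated kernel must be odd for symmetric same padding")
  if (object@attnDim %% object@attnHeads != 0L)
    msg <- c(msg, "attnDim must be divisible by attnHeads")
  if (object@dilatedOut != object@attnDim)
    msg <- c(msg, "dilated layer must output the attention width")
  if (object@qBits < 1L) msg <- c(msg, "qBits must be >= 1")
  if (object@dilation < 1L) msg <- c(msg, "dilation must be >= 1")
  if (length(msg) == 0L) {
    p <- countParameters(object)
    if (p > object@parameterBudget)
      msg <- c(msg, sprintf("parameter count %d exceeds budget %d",
                            p, object@parameterBudget))
  }
  if (length(msg)) msg else TRUE
})

#' Trained LTY-CNN model
#'
#' @slot config the [ModelConfig-class] the weights were trained under.
#' @slot weights named list of weight matrices/vectors (see
#'   [initWeights()]).
#' @slot inputScale scalar the input sequences are divided by before the
#'   forward pass (the training-set standard deviation).
#' @slot lossCurve mean training cross-entropy per epoch.
#' @export
setClass("TrainedModel",
  representation(
    config = "ModelConfig",
    weights = "list",
    inputScale = "numeric",
    lossCurve = "numeric"
  )
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@signal), ncol(object@signal),
              object@fs, ncol(object@signal) / object@fs))
  cat(sprintf("  annotations: %d seizure interval(s)\n", nrow(object@annotations)))
})

setMethod("show", "EEGWindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("EEGWindowSet: %d window(s) of %g s (%d channels x %d samples @ %g Hz)\n",
              d[3], object@windowS, d[1], d[2], object@fs))
  cat(sprintf("  labels: %d background, %d seizure\n",
              sum(object@labels == 0L), sum(object@labels == 1L)))
})

setMethod("show", "SpectrogramArray", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectrogramArray: %d channel(s) x %d frames x %d bins (%g-%g Hz)\n",
              d[1], d[2], d[3], min(object@binFreqs), max(object@binFreqs)))
})

setMethod("show", "PCABasis", function(object) {
  cat(sprintf("PCABasis: %d -> %d components (fitted on %d frames)\n",
              nrow(object@rotation), object@k, object@nTrain))
  ev <- explainedVariance(object)
  cat(sprintf("  cumulative explained variance at k: %.3f\n", sum(ev)))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d-dim x %d-step input\n",
              object@inputDim, object@seqLen))
  cat(sprintf("  branches: kernels [%s], channels [%s]; dilated k=%d d=%d -> %d ch (%d-bit)\n",
              paste(object@branchKernels, collapse = ","),
              paste(object@branchChannels, collapse = ","),
              object@dilatedKernel, object@dilation, object@dilatedOut,
              object@qBits))
  cat(sprintf("  attention: %d heads x %d dims; classes: %d\n",
              object@attnHeads, object@attnDim %/% object@attnHeads,
              object@nClasses))
  cat(sprintf("  parameters: %d (budget %d)\n", countParameters(object),
              object@parameterBudget))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %d parameters, %d training epoch(s), final loss %.4f\n",
              countParameters(object@config), length(object@lossCurve),
              if (length(object@lossCurve)) utils::tail(object@lossCurve, 1) else NA_real_))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for pipeline objects
#'
#' Small generic accessors used across the pipeline: sampling rate, channel
#' names, annotations, window count and labels.
#'
#' @param object a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGWindowSet", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) rownames(object@signal))
#' @rdname accessors
#' @export
setMethod("channelNames", "SpectrogramArray", function(object) object@channelNames)

#' @rdname accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "EEGRecording", function(object) object@annotations)

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "EEGRecording", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(object) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setMethod("recordingDuration", "EEGRecording",
          function(object) ncol(object@signal) / object@fs)

#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setMethod("nWindows", "EEGWindowSet", function(object) dim(object@windows)[3])

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(object) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setMethod("windowLabels", "EEGWindowSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setMethod("windowStarts", "EEGWindowSet", function(object) object@startS)

#' @rdname accessors
#' @export
setGeneric("windowSources", function(object) standardGeneric("windowSources"))
#' @rdname accessors
#' @export
setMethod("windowSources", "EEGWindowSet", function(object) object@sourceId)

#' Extract one window as a channels x samples matrix
#'
#' @param ws an [EEGWindowSet-class].
#' @param i window index.
#' @return numeric matrix, channels x samples.
#' @export
getWindow <- function(ws, i) {
  stopifnot(is(ws, "EEGWindowSet"), i >= 1, i <= nWindows(ws))
  ws@windows[, , i, drop = TRUE]
}

#' @rdname accessors
#' @export
setGeneric("spectrogramValues", function(object) standardGeneric("spectrogramValues"))
#' @rdname accessors
#' @export
setMethod("spectrogramValues", "SpectrogramArray", function(object) object@values)

#' Explained-variance ratios of a PCA basis
#'
#' Ratio of the variance captured by each retained component to the total
#' variance of the training frames, `d_i^2 / (n - 1) / totalVar`.
#'
#' @param basis a [PCABasis-class].
#' @return numeric vector of length `k`, nonincreasing.
#' @export
explainedVariance <- function(basis) {
  stopifnot(is(basis, "PCABasis"))
  if (basis@totalVar <= 0) return(rep(0, basis@k))
  (basis@d^2 / (basis@nTrain - 1)) / basis@totalVar
}
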