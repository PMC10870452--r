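#' Short-time Fourier transform configuration
#'
#' The reference configuration at 256 Hz uses 1-s (256-sample) Hann segments
#' with 50% overlap (128-sample hop), a one-sided spectrum at 1 Hz
#' resolution, and retains the bins from 1 Hz (the high-pass cutoff) to
#' 114 Hz (below the lower edge of the 117-123 Hz stop band). On a 16384
#' sample window this yields 127 time frames x 114 frequency bins.
#'
#' @param nfft segment length in samples (default 256).
#' @param hop hop between segments in samples (default 128).
#' @param fmin lowest retained bin frequency in Hz (default 1).
#' @param fmax highest retained bin frequency in Hz (default 114).
#' @return a list of class `STFTConfig`.
#' @export
stftConfig <- function(nfft = 256, hop = 128, fmin = 1, fmax = 114) {
  stopifnot(nfft >= 2, hop >= 1, fmin >= 0, fmax > fmin)
  structure(list(nfft = nfft, hop = hop, fmin = fmin, fmax = fmax),
            class = "STFTConfig")
}

# magnitude STFT of one channel: frames x bins (one-sided, all bins)
.stft <- function(x, nfft, hop) {
  n <- length(x)
  if (n < nfft) stop("window shorter than one STFT segment (", nfft, " samples)")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))  # Hann
  starts <- seq(1, n - nfft + 1, by = hop)
  nbin <- nfft %/% 2 + 1
  segs <- matrix(x[outer(seq_len(nfft) - 1L, starts, "+")], nrow = nfft) * win
  list(mag = t(Mod(stats::mvfft(segs))[seq_len(nbin), , drop = FALSE]),
       starts = starts)
}

#' Compute the log-magnitude spectrogram of one analysis window
#'
#' Per channel, magnitude STFT followed by `log(1 + magnitude)` compression;
#' only bins in `[fmin, fmax]` are retained.
#'
#' @param window channels x samples numeric matrix (one analysis window),
#'   or an [EEGWindowSet-class] plus index via [getWindow()].
#' @param fs sampling rate in Hz (default 256).
#' @param stft an [stftConfig()].
#' @param channelNames optional channel names (defaults to rownames).
#' @return a [SpectrogramArray-class]; at the reference settings each
#'   channel plane is 127 frames x 114 bins.
#' @export
computeSpectrogram <- function(window, fs = 256, stft = stftConfig(),
                               channelNames = rownames(window)) {
  window <- as.matrix(window)
  stopifnot(inherits(stft, "STFTConfig"))
  binFreqs <- (seq_len(stft$nfft %/% 2 + 1) - 1) * fs / stft$nfft
  keep <- which(binFreqs >= stft$fmin & binFreqs <= stft$fmax)
  first <- .stft(window[1, ], stft$nfft, stft$hop)
  nFrames <- nrow(first$mag)
  vals <- array(0, dim = c(nrow(window), nFrames, length(keep)))
  vals[1, , ] <- log1p(first$mag[, keep])
  if (nrow(window) > 1)
    for (ch in 2:nrow(window))
      vals[ch, , ] <- log1p(.stft(window[ch, ], stft$nfft, stft$hop)$mag[, keep])
  if (is.null(channelNames)) channelNames <- paste0("CH", seq_len(nrow(window)))
  new("SpectrogramArray", values = vals,
      frameTimes = (first$starts - 1 + stft$nfft / 2) / fs,
      binFreqs = binFreqs[keep], channelNames = channelNames)
}

#' Pearson correlation between EEG channels
#'
#' @param rec an [EEGRecording-class] with at least 2 samples per channel.
#' @return symmetric channels x channels correlation matrix with unit
#'   diagonal. A zero-variance channel yields a warning and zeros in its
#'   row/column (diagonal kept at 1).
#' @export
channelCorrelation <- function(rec) {
  stopifnot(is(rec, "EEGRecording"), ncol(rec@signal) >= 2)
  v <- apply(rec@signal, 1, stats::var)
  flat <- v == 0
  m <- diag(nrow(rec@signal))
  ok <- which(!flat)
  if (length(ok) >= 2)
    m[ok, ok] <- stats::cor(t(rec@signal[ok, , drop = FALSE]))
  if (any(flat))
    warning("zero-variance channel(s): ",
            paste(channelNames(rec)[flat], collapse = ", "),
            "; correlations set to 0")
  dimnames(m) <- list(channelNames(rec), channelNames(rec))
  m
}

#' Fit a principal-component basis by singular value decomposition
#'
#' Centers the frames and computes `X = U D V^T`; the basis keeps the first
#' `k` right singular vectors, the corresponding singular values, and the
#' total variance. To honour the train/test leakage contract, fit only on
#' training frames.
#'
#' @param frames n x input_dim numeric matrix, n > k.
#' @param k number of components to retain (default 64).
#' @return a [PCABasis-class].
#' @export
fitPCA <- function(frames, k = 64) {
  frames <- as.matrix(frames)
  n <- nrow(frames)
  p <- ncol(frames)
  if (n <= k) stop("need more frames than components (n = ", n, ", k = ", k, ")")
  if (k > p) stop("k cannot exceed the frame dimension (", p, ")")
  ctr <- colMeans(frames)
  X <- sweep(frames, 2, ctr)
  # eigendecomposition of the smaller Gram matrix (equivalent to the SVD)
  if (n >= p) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    V <- e$vectors[, seq_len(k), drop = FALSE]
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    U <- e$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(X, U)
    nz <- d[seq_len(k)] > max(d, 1e-300) * 1e-12
    V[, nz] <- sweep(V[, nz, drop = FALSE], 2, d[seq_len(k)][nz], "/")
    if (any(!nz)) {
      # rank-deficient: complete the basis orthonormally (deterministic)
      Vfull <- qr.Q(qr(cbind(V[, nz, drop = FALSE],
                             diag(p)[, seq_len(k), drop = FALSE])))
      V[, !nz] <- Vfull[, sum(nz) + seq_len(sum(!nz)), drop = FALSE]
    }
  }
  new("PCABasis", center = ctr, rotation = V,
      d = d[seq_len(k)], k = as.integer(k),
      totalVar = sum(X^2) / (n - 1), nTrain = as.integer(n))
}

#' Project frames onto a fitted PCA basis
#'
#' `Y = (frames - center) W`.
#'
#' @param frames n x input_dim matrix.
#' @param basis a [PCABasis-class] with matching input dimension.
#' @return n x k score matrix.
#' @export
applyPCA <- function(frames, basis) {
  frames <- as.matrix(frames)
  stopifnot(is(basis, "PCABasis"))
  if (ncol(frames) != nrow(basis@rotation))
    stop("frame dimension ", ncol(frames), " does not match basis input ",
         nrow(basis@rotation))
  sweep(frames, 2, basis@center) %*% basis@rotation
}

#' Flatten a spectrogram into per-frame feature rows
#'
#' One row per time frame: the channels x bins plane of that frame,
#' vectorised channel-major (all channels of bin 1, then bin 2, ...). This
#' is the frame layout the PCA basis is fitted on (input dimension
#' channels x bins = 18 x 114 = 2052 at the reference settings).
#'
#' @param spect a [SpectrogramArray-class].
#' @return time_frames x (channels * bins) matrix.
#' @export
spectrogramFrames <- function(spect) {
  stopifnot(is(spect, "SpectrogramArray"))
  d <- dim(spect@values)
  out <- matrix(0, nrow = d[2], ncol = d[1] * d[3])
  for (j in seq_len(d[2])) out[j, ] <- as.vector(spect@values[, j, ])
  out
}

#' Turn one window's spectrogram into the model input sequence
#'
#' Each of the time frames is flattened across channels and frequency and
#' projected by the PCA basis, yielding the classifier input: a sequence of
#' 64-dimensional feature vectors (127 x 64 at the reference settings).
#'
#' @param spect a [SpectrogramArray-class].
#' @param basis a [PCABasis-class] fitted on flattened frames of dimension
#'   channels x bins.
#' @return time_frames x k numeric matrix.
#' @export
windowsToSequences <- function(spect, basis) {
  stopifnot(is(spect, "SpectrogramArray"), is(basis, "PCABasis"))
  d <- dim(spect@values)
  if (d[1] * d[3] != nrow(basis@rotation))
    stop("basis input dimension ", nrow(basis@rotation),
         " does not match channels x bins = ", d[1] * d[3])
  applyPCA(spectrogramFrames(spect), basis)
}
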