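#' Filter specification
#'
#' Describes one zero-phase Butterworth filtering stage. Band-stop filters
#' take one or more `[low, high]` edge pairs (the powerline defaults are
#' 57-63 Hz and 117-123 Hz); the high-pass takes a single cutoff (default
#' 1 Hz). The printed transfer-function sketches of first-order magnitude
#' responses are honoured as response contracts (stop-band attenuation,
#' passband flatness) rather than as literal discrete filters.
#'
#' @param kind "bandstop" or "highpass".
#' @param bandEdges for "bandstop": list of increasing `[low, high]` pairs in
#'   Hz; for "highpass": the cutoff frequency in Hz.
#' @param order Butterworth order per section (default 4).
#' @param zeroPhase apply forward-backward (`filtfilt`) so the realized
#'   filter has no group delay (default TRUE).
#' @return a validated list of class `FilterSpec`.
#' @export
filterSpec <- function(kind = c("bandstop", "highpass"),
                       bandEdges = if (match.arg(kind) == "bandstop")
                         list(c(57, 63), c(117, 123)) else 1,
                       order = 4, zeroPhase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandstop") {
    if (!is.list(bandEdges)) bandEdges <- list(bandEdges)
    for (b in bandEdges)
      if (length(b) != 2 || b[1] >= b[2] || b[1] <= 0)
        stop("band edges must be strictly increasing positive pairs")
  } else {
    if (length(bandEdges) != 1 || bandEdges <= 0)
      stop("high-pass cutoff must be a single positive frequency")
  }
  structure(list(kind = kind, bandEdges = bandEdges, order = order,
                 zeroPhase = zeroPhase), class = "FilterSpec")
}

.applyFilt <- function(x, flt, zeroPhase) {
  if (zeroPhase) signal::filtfilt(flt, x) else signal::filter(flt, x)
}

.resampleVector <- function(x, fsIn, fsOut) {
  if (fsIn == fsOut) return(x)
  ratio <- fsIn / fsOut
  if (abs(ratio - round(ratio)) < 1e-9) {
    signal::decimate(x, round(ratio), ftype = "fir")
  } else {
    fr <- .ratApprox(fsOut / fsIn)
    signal::resample(x, fr[1], fr[2])
  }
}

.ratApprox <- function(x, maxDen = 1024) {
  den <- seq_len(maxDen)
  err <- abs(x * den - round(x * den))
  d <- den[which.min(err)]
  c(round(x * d), d)
}

#' Downsample a recording
#'
#' Anti-aliased reduction of the sampling rate (FIR polyphase decimation for
#' integer ratios, rational polyphase resampling otherwise). Annotations are
#' in seconds and are unchanged. Upsampling is refused.
#'
#' @param rec an [EEGRecording-class].
#' @param targetFs target sampling rate in Hz (default 256).
#' @return the resampled recording.
#' @export
resampleRecording <- function(rec, targetFs = 256) {
  stopifnot(is(rec, "EEGRecording"))
  if (targetFs > rec@fs)
    stop("upsampling requested (", rec@fs, " -> ", targetFs,
         " Hz); only downsampling is supported")
  if (targetFs == rec@fs) return(rec)
  out <- t(apply(rec@signal, 1, .resampleVector, fsIn = rec@fs,
                 fsOut = targetFs))
  EEGRecording(out, targetFs, channelNames = channelNames(rec),
               annotations = rec@annotations, subjectId = rec@subjectId)
}

#' Remove powerline interference with zero-phase band-stop filters
#'
#' Applies one 4th-order Butterworth band-stop section per stop band,
#' forward-backward. At the defaults this attenuates 60 Hz and 120 Hz by
#' well over 40 dB while leaving 10 Hz and 100 Hz within 1 dB of unity.
#'
#' @param rec an [EEGRecording-class].
#' @param spec a band-stop [filterSpec()].
#' @return the filtered recording.
#' @export
applyBandstop <- function(rec, spec = filterSpec("bandstop")) {
  stopifnot(is(rec, "EEGRecording"), inherits(spec, "FilterSpec"),
            spec$kind == "bandstop")
  nyq <- rec@fs / 2
  for (b in spec$bandEdges)
    if (b[2] >= nyq)
      stop("band edge ", b[2], " Hz is at or above Nyquist (", nyq, " Hz)")
  sig <- rec@signal
  for (b in spec$bandEdges) {
    flt <- signal::butter(spec$order, b / nyq, type = "stop")
    for (ch in seq_len(nrow(sig)))
      sig[ch, ] <- .applyFilt(sig[ch, ], flt, spec$zeroPhase)
  }
  EEGRecording(sig, rec@fs, channelNames = channelNames(rec),
               annotations = rec@annotations, subjectId = rec@subjectId)
}

#' Remove slow drift with a zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward-backward, followed by
#' removal of the residual mean (the forward-backward pass leaves a small
#' boundary-transient DC offset), so the output mean is numerically zero.
#'
#' @param rec an [EEGRecording-class].
#' @param fc cutoff frequency in Hz (default 1).
#' @param order Butterworth order (default 4).
#' @return the filtered recording.
#' @export
applyHighpass <- function(rec, fc = 1, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  if (fc <= 0 || fc >= rec@fs / 2)
    stop("cutoff must satisfy 0 < fc < fs/2")
  flt <- signal::butter(order, fc / (rec@fs / 2), type = "high")
  sig <- rec@signal
  for (ch in seq_len(nrow(sig))) {
    y <- signal::filtfilt(flt, sig[ch, ])
    sig[ch, ] <- y - mean(y)
  }
  EEGRecording(sig, rec@fs, channelNames = channelNames(rec),
               annotations = rec@annotations, subjectId = rec@subjectId)
}

#' Standard preprocessing chain
#'
#' Resample to 256 Hz, remove powerline bands, high-pass at 1 Hz.
#'
#' @param rec an [EEGRecording-class].
#' @param targetFs target sampling rate (default 256).
#' @return the preprocessed recording.
#' @export
preprocessRecording <- function(rec, targetFs = 256) {
  rec <- resampleRecording(rec, targetFs)
  rec <- applyBandstop(rec)
  applyHighpass(rec)
}

#' Segment a recording into fixed-length windows
#'
#' Windows start at `0, stride, 2 stride, ...` seconds while
#' `start + windowS <= duration`. Labels are initialised to 0; use
#' [labelWindows()] to assign them. At the reference 64 s / 256 Hz each
#' window holds 16384 samples.
#'
#' @param rec an [EEGRecording-class].
#' @param windowS window length in seconds (default 64).
#' @param strideS hop between window starts in seconds (default 64,
#'   i.e. non-overlapping).
#' @return an [EEGWindowSet-class] (empty, with a warning, if the recording
#'   is shorter than one window).
#' @export
segmentWindows <- function(rec, windowS = 64, strideS = 64) {
  stopifnot(is(rec, "EEGRecording"), windowS > 0, strideS > 0)
  fs <- rec@fs
  wlen <- round(windowS * fs)
  dur <- recordingDuration(rec)
  starts <- seq(0, by = strideS, length.out = max(0, floor((dur - windowS) / strideS) + 1))
  if (dur < windowS) {
    warning("recording shorter than one window; returning an empty window set")
    starts <- numeric(0)
  }
  nw <- length(starts)
  w <- array(0, dim = c(nrow(rec@signal), wlen, nw))
  for (i in seq_len(nw)) {
    i0 <- round(starts[i] * fs) + 1
    w[, , i] <- rec@signal[, i0:(i0 + wlen - 1)]
  }
  new("EEGWindowSet", windows = w, labels = rep(0L, nw), startS = starts,
      sourceId = rep(rec@subjectId, nw), fs = fs, windowS = windowS)
}

.overlapSeconds <- function(start, end, ann) {
  if (nrow(ann) == 0) return(rep(0, length(start)))
  vapply(seq_along(start), function(i) {
    sum(pmax(0, pmin(end[i], ann$end) - pmax(start[i], ann$start)))
  }, 0)
}

#' Label windows against seizure annotations
#'
#' A window is labelled 1 (seizure) when its overlap with annotated seizure
#' intervals is at least `minOverlap` of the window length, and 0 when the
#' overlap is zero. Windows with intermediate overlap are ambiguous: by
#' default they are dropped; they can instead be kept as seizure or as
#' background.
#'
#' @param ws an [EEGWindowSet-class].
#' @param annotations annotations data.frame (`start`, `end`, `label`).
#' @param minOverlap fraction of the window that must be ictal for label 1
#'   (default 0.5).
#' @param ambiguous policy for windows with partial overlap below
#'   `minOverlap`: "drop" (default), "seizure" or "background".
#' @return the labelled (possibly reduced) window set.
#' @export
labelWindows <- function(ws, annotations,
                         minOverlap = 0.5,
                         ambiguous = c("drop", "seizure", "background")) {
  stopifnot(is(ws, "EEGWindowSet"))
  ambiguous <- match.arg(ambiguous)
  ov <- .overlapSeconds(ws@startS, ws@startS + ws@windowS, annotations)
  lab <- ifelse(ov >= minOverlap * ws@windowS, 1L, 0L)
  keep <- rep(TRUE, length(lab))
  mid <- ov > 0 & ov < minOverlap * ws@windowS
  if (ambiguous == "drop") keep[mid] <- FALSE
  if (ambiguous == "seizure") lab[mid] <- 1L
  if (ambiguous == "background") lab[mid] <- 0L
  new("EEGWindowSet",
      windows = ws@windows[, , keep, drop = FALSE],
      labels = as.integer(lab[keep]), startS = ws@startS[keep],
      sourceId = ws@sourceId[keep], fs = ws@fs, windowS = ws@windowS)
}

#' Oversample the seizure class by overlapped windowing
#'
#' Balances the class counts by extracting additional seizure windows from
#' annotated seizure spans of the source recording at a small stride
#' (default 16 s, i.e. 75% overlap at the reference 64-s window), until the
#' minority/majority ratio reaches `targetRatio` or the spans are exhausted.
#' Existing windows, their labels and background windows are never touched
#' or duplicated, and every added window records its start time.
#'
#' @param ws a labelled [EEGWindowSet-class] cut from `rec`.
#' @param rec the filtered source [EEGRecording-class] (with annotations).
#' @param minorityStrideS stride inside seizure spans in seconds (default 16).
#' @param targetRatio stop once `minority / majority >= targetRatio`
#'   (default 1, full balance).
#' @return the augmented window set.
#' @export
balanceByOverlap <- function(ws, rec, minorityStrideS = 16, targetRatio = 1) {
  stopifnot(is(ws, "EEGWindowSet"), is(rec, "EEGRecording"))
  ann <- rec@annotations
  if (nrow(ann) == 0) {
    warning("no seizure annotations; window set returned unchanged")
    return(ws)
  }
  if (targetRatio <= 0) return(ws)
  nMin <- sum(ws@labels == 1L)
  nMaj <- sum(ws@labels == 0L)
  if (nMaj == 0 || nMin / nMaj >= targetRatio) return(ws)

  fs <- ws@fs
  wlen <- round(ws@windowS * fs)
  candidates <- unlist(lapply(seq_len(nrow(ann)), function(s) {
    last <- ann$end[s] - ws@windowS
    if (last < ann$start[s]) return(numeric(0))
    seq(ann$start[s], last, by = minorityStrideS)
  }))
  existing <- ws@startS[ws@sourceId == rec@subjectId]
  candidates <- candidates[!candidates %in% existing]

  added <- list(); addedStart <- numeric(0)
  for (st in candidates) {
    if (nMin / nMaj >= targetRatio) break
    i0 <- round(st * fs) + 1
    if (i0 + wlen - 1 > ncol(rec@signal)) next
    added[[length(added) + 1]] <- rec@signal[, i0:(i0 + wlen - 1)]
    addedStart <- c(addedStart, st)
    nMin <- nMin + 1
  }
  if (length(added) == 0) return(ws)
  nAdd <- length(added)
  w <- array(0, dim = c(dim(ws@windows)[1], wlen, nWindows(ws) + nAdd))
  w[, , seq_len(nWindows(ws))] <- ws@windows
  for (i in seq_len(nAdd)) w[, , nWindows(ws) + i] <- added[[i]]
  new("EEGWindowSet", windows = w,
      labels = c(ws@labels, rep(1L, nAdd)),
      startS = c(ws@startS, addedStart),
      sourceId = c(ws@sourceId, rep(rec@subjectId, nAdd)),
      fs = ws@fs, windowS = ws@windowS)
}

#' Concatenate window sets
#'
#' @param ... [EEGWindowSet-class] objects with identical window geometry.
#' @return the combined window set.
#' @export
combineWindowSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is(sets[[1]], "EEGWindowSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  ref <- sets[[1]]
  for (s in sets[-1])
    if (s@fs != ref@fs || s@windowS != ref@windowS ||
        dim(s@windows)[1] != dim(ref@windows)[1])
      stop("window sets have incompatible geometry")
  ns <- vapply(sets, nWindows, 0L)
  total <- sum(ns)
  w <- array(0, dim = c(dim(ref@windows)[1], dim(ref@windows)[2], total))
  off <- 0
  for (s in sets) {
    if (nWindows(s) > 0) w[, , off + seq_len(nWindows(s))] <- s@windows
    off <- off + nWindows(s)
  }
  new("EEGWindowSet", windows = w,
      labels = unlist(lapply(sets, function(s) s@labels)),
      startS = unlist(lapply(sets, function(s) s@startS)),
      sourceId = unlist(lapply(sets, function(s) s@sourceId)),
      fs = ref@fs, windowS = ref@windowS)
}
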