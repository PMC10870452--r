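#' Standard 18-channel bipolar montage
#'
#' The 18 bipolar double-banana derivations conventionally used for scalp
#' epilepsy assessment (the CHB-MIT channel convention). Used as the default
#' analysis montage and as the default channel names of the simulator.
#'
#' @return character vector of 18 channel labels.
#' @export
standardMontage18 <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ")
}

# pad/truncate an ASCII field to exactly n bytes
.edfField <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  sprintf(paste0("%-", n, "s"), x)
}

.edfNum <- function(x, n) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > n) s <- substr(format(x, digits = n - 2, nsmall = 0,
                                       scientific = FALSE), 1, n)
  .edfField(s, n)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. The physical range is set
#' symmetrically to cover the signal, so the reconstruction error per sample
#' is at most `(physical range) / 2^16`. The header date/time fields are
#' fixed constants so that identical recordings produce byte-identical files.
#'
#' @param rec an [EEGRecording-class]; the sampling rate must be a positive
#'   integer and the duration a whole number of seconds.
#' @param path output file path.
#' @param physMax symmetric physical maximum in microvolts; defaults to the
#'   smallest integer >= max absolute signal value (at least 1).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physMax = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  sig <- rec@signal
  fs <- rec@fs
  if (fs != round(fs) || fs <= 0)
    stop("EDF writer requires an integer sampling rate")
  if (ncol(sig) %% fs != 0)
    stop("EDF writer requires a whole number of seconds of signal")
  nrec <- ncol(sig) %/% fs
  ns <- nrow(sig)
  if (is.null(physMax)) physMax <- max(1, ceiling(max(abs(sig))))
  if (max(abs(sig)) > physMax)
    stop("signal exceeds the representable EDF physical range; rescale first")
  digMin <- -32768L; digMax <- 32767L
  physMin <- -physMax

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfField("0", 8),
    .edfField(rec@subjectId, 80),
    .edfField("ltycnn synthetic recording", 80),
    .edfField("01.01.00", 8),
    .edfField("00.00.00", 8),
    .edfField(256 * (ns + 1), 8),
    .edfField("", 44),
    .edfField(nrec, 8),
    .edfField("1", 8),
    .edfField(ns, 4)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  lab <- rownames(sig)
  sigHdr <- paste0(
    paste(vapply(lab, .edfField, "", n = 16), collapse = ""),
    paste(rep(.edfField("", 80), ns), collapse = ""),
    paste(rep(.edfField("uV", 8), ns), collapse = ""),
    paste(rep(.edfNum(physMin, 8), ns), collapse = ""),
    paste(rep(.edfNum(physMax, 8), ns), collapse = ""),
    paste(rep(.edfField(digMin, 8), ns), collapse = ""),
    paste(rep(.edfField(digMax, 8), ns), collapse = ""),
    paste(rep(.edfField("", 80), ns), collapse = ""),
    paste(rep(.edfField(fs, 8), ns), collapse = ""),
    paste(rep(.edfField("", 32), ns), collapse = "")
  )
  writeChar(sigHdr, con, eos = NULL, useBytes = TRUE)

  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((sig - physMin) * scale) + digMin
  dig <- pmin(pmax(dig, digMin), digMax)
  storage.mode(dig) <- "integer"
  # one record = one second: all channels' samples for that second, in order
  idx <- matrix(seq_len(ncol(sig)), nrow = fs)
  for (r in seq_len(nrec)) {
    block <- t(dig[, idx[, r], drop = FALSE])  # fs x ns, channel-major records
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal EDF reader for 16-bit polygraphic recordings: parses the header,
#' reads all data records and rescales to physical units. If channels carry
#' different per-channel sampling rates, all channels are resampled to the
#' minimum rate before the recording is returned.
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, rownames set),
#'   `fs` and `subjectId`. Use [readRecording()] for the full object with
#'   annotations.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("malformed EDF: bad version field")
  subjectId <- rd(80)
  rd(80); rd(8); rd(8)
  hdrBytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  recDur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdrBytes, nrec, recDur, ns)) || ns < 1)
    stop("malformed EDF: unparsable header fields")
  if (hdrBytes != 256 * (ns + 1)) stop("malformed EDF: header size mismatch")
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80)
  fields(8)
  physMin <- as.numeric(fields(8))
  physMax <- as.numeric(fields(8))
  digMin <- as.numeric(fields(8))
  digMax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))  # samples per record, per signal
  fields(32)
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("malformed EDF: unparsable signal headers")

  total <- sum(spr) * nrec
  raw <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
  if (length(raw) < total) stop("malformed EDF: truncated data section")

  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- numeric(spr[i] * nrec)
  offs <- c(0, cumsum(spr))
  recLen <- sum(spr)
  for (r in seq_len(nrec)) {
    base <- (r - 1) * recLen
    for (i in seq_len(ns)) {
      seg <- raw[(base + offs[i] + 1):(base + offs[i + 1])]
      chans[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- seg
    }
  }
  for (i in seq_len(ns)) {
    sc <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    chans[[i]] <- (chans[[i]] - digMin[i]) * sc + physMin[i]
  }
  fsAll <- spr / recDur
  fs <- min(fsAll)
  if (any(fsAll != fs)) {
    for (i in which(fsAll > fs))
      chans[[i]] <- .resampleVector(chans[[i]], fsAll[i], fs)
  }
  nSamp <- min(lengths(chans))
  sig <- do.call(rbind, lapply(chans, function(x) x[seq_len(nSamp)]))
  rownames(sig) <- labels
  list(signal = sig, fs = fs, subjectId = subjectId)
}

#' Read seizure annotations from a JSON sidecar
#'
#' The sidecar is a JSON array of objects with fields `start_s`, `end_s`
#' and `label` (half-open intervals in seconds).
#'
#' @param path sidecar path.
#' @return annotations data.frame with columns `start`, `end`, `label`.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation sidecar not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0 || (is.data.frame(x) && nrow(x) == 0))
    return(emptyAnnotations())
  data.frame(start = as.numeric(x$start_s), end = as.numeric(x$end_s),
             label = as.character(x$label), stringsAsFactors = FALSE)
}

#' @rdname readAnnotations
#' @param annotations annotations data.frame (`start`, `end`, `label`).
#' @export
writeAnnotations <- function(annotations, path) {
  out <- data.frame(start_s = annotations$start, end_s = annotations$end,
                    label = annotations$label)
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an EDF recording with optional seizure annotations
#'
#' @param edfPath path to an EDF file.
#' @param annotationPath optional path to a JSON annotation sidecar; if
#'   missing, the recording carries no annotations.
#' @return An [EEGRecording-class].
#' @export
readRecording <- function(edfPath, annotationPath = NULL) {
  e <- readEDF(edfPath)
  ann <- if (is.null(annotationPath)) emptyAnnotations()
         else readAnnotations(annotationPath)
  dur <- ncol(e$signal) / e$fs
  if (nrow(ann) > 0 && (any(ann$start < 0) || any(ann$end > dur + 1e-9)))
    stop("annotation interval outside the recording (duration ", dur, " s)")
  EEGRecording(e$signal, e$fs, annotations = ann, subjectId = e$subjectId)
}

.normalizeLabel <- function(x) {
  gsub("[[:space:]_]+", "", toupper(gsub("-", "-", x)))
}

#' Select and order channels by a montage
#'
#' Subsets a recording to the named montage, in montage order. Matching is
#' case-insensitive and ignores whitespace, so common EDF label dialects
#' ("FP1-F7", "fp1-f7 ", "FP1 -F7") resolve to the same channel.
#'
#' @param rec an [EEGRecording-class].
#' @param montage character vector of channel names (default the 18-channel
#'   bipolar analysis montage of [standardMontage18()]).
#' @return the recording restricted to the montage channels, in order.
#' @export
selectChannels <- function(rec, montage = standardMontage18()) {
  stopifnot(is(rec, "EEGRecording"))
  have <- .normalizeLabel(channelNames(rec))
  want <- .normalizeLabel(montage)
  idx <- match(want, have)
  if (anyNA(idx))
    stop("montage channel(s) not present in recording: ",
         paste(montage[is.na(idx)], collapse = ", "))
  EEGRecording(rec@signal[idx, , drop = FALSE], rec@fs,
               channelNames = montage, annotations = rec@annotations,
               subjectId = rec@subjectId)
}
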