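#' Configuration for the synthetic EEG simulator
#'
#' Describes one simulated multichannel scalp EEG recording: stationary
#' background activity (1/f-shaped broadband noise plus alpha- and beta-band
#' oscillations and powerline contamination at 60 and 120 Hz) with a chosen
#' number of annotated ictal episodes of rhythmic spike-wave-like activity.
#'
#' @param nChannels number of channels (default 18, the analysis montage).
#' @param duration recording length in whole seconds.
#' @param fs sampling rate in Hz (default 256); must be at least twice the
#'   powerline harmonic (240 Hz) so that the contamination is representable.
#' @param nSeizures number of ictal episodes.
#' @param seizureDurationRange `[min, max]` episode length in seconds.
#' @param ictalAmplitudeGain amplitude of the ictal rhythm relative to the
#'   background RMS, >= 1.
#' @param ictalFreq fundamental frequency of the ictal rhythm in Hz
#'   (default 3, the classic spike-wave band).
#' @param powerlineFreq mains frequency in Hz (default 60; a harmonic at
#'   twice this frequency is added as well).
#' @param backgroundAlphaPower variance (uV^2) of the alpha-band oscillation.
#' @param backgroundNoisePower variance (uV^2) of the 1/f broadband noise.
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical recordings.
#' @return a validated list of class `SynthConfig`.
#' @export
synthConfig <- function(nChannels = 18, duration = 768, fs = 256,
                        nSeizures = 2, seizureDurationRange = c(96, 160),
                        ictalAmplitudeGain = 6, ictalFreq = 3,
                        powerlineFreq = 60,
                        backgroundAlphaPower = 200,
                        backgroundNoisePower = 600,
                        seed = 1L) {
  cfg <- list(nChannels = as.integer(nChannels), duration = duration, fs = fs,
              nSeizures = as.integer(nSeizures),
              seizureDurationRange = seizureDurationRange,
              ictalAmplitudeGain = ictalAmplitudeGain, ictalFreq = ictalFreq,
              powerlineFreq = powerlineFreq,
              backgroundAlphaPower = backgroundAlphaPower,
              backgroundNoisePower = backgroundNoisePower,
              seed = as.integer(seed))
  if (cfg$nChannels < 1) stop("nChannels must be >= 1")
  if (cfg$duration <= 0) stop("duration must be positive")
  if (length(cfg$seizureDurationRange) != 2 ||
      cfg$seizureDurationRange[1] > cfg$seizureDurationRange[2] ||
      cfg$seizureDurationRange[1] <= 0)
    stop("seizureDurationRange must be an increasing positive pair")
  if (cfg$nSeizures < 0) stop("nSeizures must be >= 0")
  if (cfg$nSeizures * cfg$seizureDurationRange[2] >= cfg$duration)
    stop("episodes cannot fit: nSeizures x max duration must be < duration")
  if (cfg$ictalAmplitudeGain < 1) stop("ictalAmplitudeGain must be >= 1")
  if (cfg$fs < 2 * 2 * cfg$powerlineFreq)
    stop("fs must be >= twice the powerline harmonic (", 4 * cfg$powerlineFreq,
         " Hz)")
  class(cfg) <- "SynthConfig"
  cfg
}

# 1/f-amplitude-shaped Gaussian noise with a target variance
.pinkNoise <- function(n, fs, targetVar) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                  # two-sided frequency axis
  shape <- ifelse(f < 0.5, 0, 1 / sqrt(f))  # power slope -1; kill drift < 0.5 Hz
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * sqrt(targetVar) / stats::sd(x)
}

# amplitude-modulated band oscillation (random frequency within band)
.bandOscillation <- function(t, band, targetVar) {
  f0 <- runif(1, band[1], band[2])
  phase <- runif(1, 0, 2 * pi)
  # slow random amplitude modulation (waxing/waning rhythm)
  am <- 1 + 0.5 * sin(2 * pi * runif(1, 0.05, 0.15) * t + runif(1, 0, 2 * pi))
  x <- am * sin(2 * pi * f0 * t + phase)
  x * sqrt(targetVar) / stats::sd(x)
}

# place nSeizures disjoint intervals by rejection sampling; 8 s guard margins
.placeSeizures <- function(cfg) {
  if (cfg$nSeizures == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  margin <- min(8, (cfg$duration - cfg$nSeizures * cfg$seizureDurationRange[2]) /
                     (2 * (cfg$nSeizures + 1)))
  if (margin <= 0)
    stop("could not place ", cfg$nSeizures, " non-overlapping episodes in ",
         cfg$duration, " s; shorten the episodes or extend the recording")
  for (attempt in seq_len(2000)) {
    durs <- runif(cfg$nSeizures, cfg$seizureDurationRange[1],
                  cfg$seizureDurationRange[2])
    starts <- runif(cfg$nSeizures, margin, cfg$duration - margin - durs)
    o <- order(starts)
    starts <- starts[o]; durs <- durs[o]
    ends <- starts + durs
    if (cfg$nSeizures == 1 || all(starts[-1] - ends[-cfg$nSeizures] >= margin))
      return(data.frame(start = starts, end = ends,
                        label = rep("seizure", cfg$nSeizures),
                        stringsAsFactors = FALSE))
  }
  stop("could not place ", cfg$nSeizures, " non-overlapping episodes in ",
       cfg$duration, " s; shorten the episodes or extend the recording")
}

#' Simulate a multichannel EEG recording with annotated seizures
#'
#' Background activity per channel is 1/f-shaped noise plus alpha (8-12 Hz)
#' and beta (18-25 Hz) oscillations with per-channel random phase, and
#' powerline sinusoids at 60 and 120 Hz. Each ictal episode adds a rhythmic
#' spike-wave-like waveform (fundamental plus two exponentially decaying
#' harmonics) with amplitude `ictalAmplitudeGain` times the background RMS,
#' phase-locked across a random subset of at least half the channels, with
#' 1-s cosine on/off ramps. Amplitudes are in microvolts with a background
#' RMS near 30 uV.
#'
#' @param config a [synthConfig()].
#' @return an [EEGRecording-class] with exactly `nSeizures` disjoint,
#'   half-open annotated intervals.
#' @export
simulateRecording <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  n <- round(config$duration * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  ann <- .placeSeizures(config)

  sig <- matrix(0, nrow = config$nChannels, ncol = n)
  for (ch in seq_len(config$nChannels)) {
    x <- .pinkNoise(n, config$fs, config$backgroundNoisePower)
    x <- x + .bandOscillation(t, c(8, 12), config$backgroundAlphaPower)
    x <- x + .bandOscillation(t, c(18, 25), config$backgroundAlphaPower / 4)
    x <- x + 8 * sin(2 * pi * config$powerlineFreq * t + runif(1, 0, 2 * pi))
    x <- x + 4 * sin(2 * pi * 2 * config$powerlineFreq * t + runif(1, 0, 2 * pi))
    sig[ch, ] <- x
  }
  bgRMS <- sqrt(mean(sig^2))

  if (nrow(ann) > 0) {
    for (s in seq_len(nrow(ann))) {
      nAffected <- sample(seq(ceiling(config$nChannels / 2),
                              config$nChannels), 1)
      affected <- sample(seq_len(config$nChannels), nAffected)
      i0 <- floor(ann$start[s] * config$fs) + 1
      i1 <- min(ceiling(ann$end[s] * config$fs), n)
      ts <- t[i0:i1] - ann$start[s]
      phase <- runif(1, 0, 2 * pi)  # shared across affected channels
      wave <- sin(2 * pi * config$ictalFreq * ts + phase) +
        exp(-1) * sin(2 * pi * 2 * config$ictalFreq * ts + 2 * phase) +
        exp(-2) * sin(2 * pi * 3 * config$ictalFreq * ts + 3 * phase)
      wave <- wave / sqrt(mean(wave^2))
      ramp <- rep(1, length(ts))
      nr <- min(config$fs, floor(length(ts) / 2))  # 1-s cosine taper
      if (nr > 0) {
        up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        ramp[seq_len(nr)] <- up
        ramp[(length(ts) - nr + 1):length(ts)] <- rev(up)
      }
      ictal <- config$ictalAmplitudeGain * bgRMS * wave * ramp
      sig[affected, i0:i1] <- sweep(sig[affected, i0:i1, drop = FALSE], 2,
                                    ictal, "+")
    }
  }

  EEGRecording(sig, config$fs,
               channelNames = if (config$nChannels == 18) standardMontage18()
                              else paste0("CH", seq_len(config$nChannels)),
               annotations = ann,
               subjectId = sprintf("synth-%04d", config$seed))
}

#' Write a dataset of recordings to EDF plus annotation sidecars
#'
#' Writes one EDF file and one JSON annotation sidecar per recording, plus a
#' JSON manifest listing the files, durations and seizure counts.
#'
#' @param recordings nonempty list of [EEGRecording-class] objects.
#' @param outDir output directory (created if absent).
#' @return the manifest as a data.frame, invisibly; also written to
#'   `manifest.json` in `outDir`.
#' @export
writeDataset <- function(recordings, outDir) {
  if (length(recordings) == 0) stop("recordings must be a nonempty list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    stopifnot(is(rec, "EEGRecording"))
    base <- sprintf("recording_%03d", i)
    edf <- file.path(outDir, paste0(base, ".edf"))
    sidecar <- file.path(outDir, paste0(base, ".annotations.json"))
    writeEDF(rec, edf)
    writeAnnotations(rec@annotations, sidecar)
    data.frame(edf = basename(edf), annotations = basename(sidecar),
               subject = rec@subjectId,
               duration_s = recordingDuration(rec),
               n_channels = nrow(rec@signal),
               n_seizures = nrow(rec@annotations),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}
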