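# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

# a small simulated recording: 192 s, one ~80 s seizure, gain 5
fixtureRecording <- function() {
  if (is.null(.fixtures$rec)) {
    cfg <- synthConfig(duration = 192, nSeizures = 1,
                       seizureDurationRange = c(70, 90),
                       ictalAmplitudeGain = 5, seed = 101)
    .fixtures$rec <- simulateRecording(cfg)
  }
  .fixtures$rec
}

fixtureFiltered <- function() {
  if (is.null(.fixtures$filt))
    .fixtures$filt <- applyHighpass(applyBandstop(fixtureRecording()))
  .fixtures$filt
}

# single-channel recording wrapping an arbitrary signal vector
toneRecording <- function(x, fs) {
  EEGRecording(matrix(x, nrow = 1, dimnames = list("CH1", NULL)), fs,
               subjectId = "tone")
}

# amplitude of the frequency-f component from the full-length DFT
ampAt <- function(x, f, fs) {
  n <- length(x)
  2 * Mod(fft(x))[round(f * n / fs) + 1] / n
}

# mean band power (Welch-style: 4-s segments, periodogram average)
bandPower <- function(x, fs, band, segS = 4) {
  seg <- segS * fs
  starts <- seq(1, length(x) - seg + 1, by = seg)
  freqs <- (seq_len(seg) - 1) * fs / seg
  sel <- freqs >= band[1] & freqs <= band[2]
  mean(vapply(starts, function(s) {
    p <- Mod(fft(x[s:(s + seg - 1)]))^2 / seg
    sum(p[sel])
  }, 0))
}

# small labelled window set with a separable 5 Hz rhythm in class 1
makeTinyWindowSet <- function(n = 20, fs = 64, windowS = 4, nCh = 2,
                              seed = 42) {
  set.seed(seed)
  wlen <- windowS * fs
  labs <- rep(0:1, length.out = n)
  w <- array(rnorm(nCh * wlen * n), dim = c(nCh, wlen, n))
  t <- (seq_len(wlen) - 1) / fs
  for (i in which(labs == 1))
    w[, , i] <- w[, , i] + matrix(3 * sin(2 * pi * 5 * t), nCh, wlen,
                                  byrow = TRUE)
  new("EEGWindowSet", windows = w, labels = as.integer(labs),
      startS = (seq_len(n) - 1) * windowS,
      sourceId = rep(c("recA", "recB"), each = ceiling(n / 2))[seq_len(n)],
      fs = fs, windowS = windowS)
}

# independent brute-force oracle for AUC: concordant-pair counting
aucByPairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent naive 1-D dilated convolution oracle (triple loop, zero pad)
naiveDilatedConv <- function(seq, W, d) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]; k <- dim(W)[3]
  T <- ncol(seq)
  ctr <- (k - 1) %/% 2
  out <- matrix(0, Cout, T)
  for (j in seq_len(Cout))
    for (t in seq_len(T))
      for (m in seq_len(k)) {
        src <- t + d * (m - 1 - ctr)
        if (src >= 1 && src <= T)
          out[j, t] <- out[j, t] + sum(W[j, , m] * seq[, src])
      }
  out
}
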