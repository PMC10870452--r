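test_that("resampling at the native rate is the identity", {
  rec <- toneRecording(rnorm(512), 256)
  expect_identical(signalMatrix(resampleRecording(rec, 256)),
                   signalMatrix(rec))
})

test_that("512 -> 256 Hz halves the sample count and preserves a 5 Hz tone", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- toneRecording(sin(2 * pi * 5 * t), fs)
  out <- resampleRecording(rec, 256)
  y <- signalMatrix(out)[1, ]
  expect_equal(length(y), 2560)
  expect_equal(samplingRate(out), 256)
  n <- length(y)
  spec <- Mod(fft(y))[1:(n / 2)]
  expect_equal((which.max(spec) - 1) * 256 / n, 5)  # dominant bin still 5 Hz
  expect_lt(abs(ampAt(y, 5, 256) - 1), 0.01)        # amplitude within 1%
})

test_that("upsampling is refused and annotations survive resampling", {
  rec <- toneRecording(rnorm(1024), 256)
  expect_error(resampleRecording(rec, 512), "upsampling")
  ann <- data.frame(start = 1, end = 2, label = "seizure")
  rec2 <- EEGRecording(matrix(rnorm(2 * 2048), 2,
                              dimnames = list(c("A", "B"), NULL)),
                       512, annotations = ann)
  expect_equal(annotations(resampleRecording(rec2, 256)), ann)
})

test_that("band-stop attenuates 60 and 120 Hz by >= 40 dB and passes 10 and 100 Hz within 1 dB", {
  fs <- 256
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t) +
    sin(2 * pi * 100 * t) + sin(2 * pi * 120 * t)
  y <- signalMatrix(applyBandstop(toneRecording(x, fs)))[1, ]
  attn <- function(f) 20 * log10(ampAt(y, f, fs) / 1)
  expect_lte(attn(60), -40)
  expect_lte(attn(120), -40)
  expect_lt(abs(attn(10)), 1)
  expect_lt(abs(attn(100)), 1)
})

test_that("band-stop maps zero to zero and rejects bands at Nyquist", {
  rec <- toneRecording(rep(0, 1024), 256)
  expect_true(all(signalMatrix(applyBandstop(rec)) == 0))
  bad <- filterSpec("bandstop", list(c(120, 130)))
  expect_error(applyBandstop(rec, bad), "Nyquist")
})

test_that("high-pass rejects DC, passes 10 Hz within 1 dB, attenuates 0.2 Hz by >= 6 dB", {
  fs <- 256
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 5 + sin(2 * pi * 10 * t) + sin(2 * pi * 0.2 * t)
  y <- signalMatrix(applyHighpass(toneRecording(x, fs)))[1, ]
  expect_lte(abs(mean(y)), 1e-6 * sqrt(mean(x^2)))
  expect_lt(abs(20 * log10(ampAt(y, 10, fs))), 1)
  expect_lte(20 * log10(ampAt(y, 0.2, fs)), -6)
  expect_error(applyHighpass(toneRecording(x, fs), fc = 200), "fc")
})

test_that("filtering is linear within floating tolerance", {
  set.seed(8)
  x <- rnorm(2048)
  fs <- 256
  y1 <- signalMatrix(applyBandstop(toneRecording(3.7 * x, fs)))[1, ]
  y2 <- 3.7 * signalMatrix(applyBandstop(toneRecording(x, fs)))[1, ]
  expect_equal(y1, y2, tolerance = 1e-6)
})

test_that("segmentation produces the documented window grid", {
  # 640 s at a cheap rate, stride == window -> 10 windows
  rec <- toneRecording(rnorm(640 * 32), 32)
  ws <- segmentWindows(rec, 64, 64)
  expect_equal(nWindows(ws), 10)
  expect_equal(windowStarts(ws), seq(0, 576, by = 64))
  # 200 s, window 64, stride 16 -> floor((200-64)/16)+1 = 9 windows
  ws2 <- segmentWindows(toneRecording(rnorm(200 * 32), 32), 64, 16)
  expect_equal(nWindows(ws2), 9)
  # shorter than one window -> empty with warning
  expect_warning(ws3 <- segmentWindows(toneRecording(rnorm(32), 32), 64),
                 "empty")
  expect_equal(nWindows(ws3), 0)
})

test_that("a 64-s recording yields one window of 16384 samples at 256 Hz", {
  rec <- toneRecording(rnorm(64 * 256), 256)
  ws <- segmentWindows(rec)
  expect_equal(nWindows(ws), 1)
  expect_equal(dim(ws@windows)[2], 16384)
})

test_that("segment-then-concatenate reconstructs the trimmed signal exactly", {
  x <- rnorm(650 * 32)
  rec <- toneRecording(x, 32)
  ws <- segmentWindows(rec, 64, 64)
  rebuilt <- as.vector(vapply(seq_len(nWindows(ws)),
                              function(i) getWindow(ws, i), numeric(64 * 32)))
  expect_identical(rebuilt, x[seq_len(640 * 32)])
})

test_that("window labelling follows the 50% overlap rule with a configurable ambiguous policy", {
  fs <- 32
  rec <- EEGRecording(matrix(rnorm(2 * 320 * fs), 2,
                             dimnames = list(c("A", "B"), NULL)), fs,
                      annotations = data.frame(start = 64, end = 160,
                                               label = "seizure"))
  ws <- segmentWindows(rec, 64, 64)   # windows at 0, 64, 128, 192, 256
  lab <- labelWindows(ws, annotations(rec))
  # 0: no overlap -> 0; 64: fully inside -> 1; 128: 32/64 = 50% -> 1;
  # 192, 256: no overlap -> 0
  expect_equal(windowLabels(lab), c(0L, 1L, 1L, 0L, 0L))
  # 20/64 overlap is ambiguous: dropped by default
  rec2 <- EEGRecording(signalMatrix(rec), fs,
                       annotations = data.frame(start = 44, end = 120,
                                                label = "seizure"))
  ws2 <- segmentWindows(rec2, 64, 64)
  labD <- labelWindows(ws2, annotations(rec2))
  expect_equal(nWindows(labD), nWindows(ws2) - 1)   # 20 s overlap dropped
  labS <- labelWindows(ws2, annotations(rec2), ambiguous = "seizure")
  expect_equal(windowLabels(labS)[1], 1L)
  labB <- labelWindows(ws2, annotations(rec2), ambiguous = "background")
  expect_equal(windowLabels(labB)[1], 0L)
})

test_that("overlap balancing adds only provenance-consistent seizure windows", {
  fs <- 32
  # one 200-s seizure span inside a 640-s recording
  sig <- matrix(rnorm(2 * 640 * fs), 2, dimnames = list(c("A", "B"), NULL))
  rec <- EEGRecording(sig, fs,
                      annotations = data.frame(start = 192, end = 392,
                                               label = "seizure"))
  ws <- labelWindows(segmentWindows(rec, 64, 64), annotations(rec))
  before <- windowLabels(ws)
  bal <- balanceByOverlap(ws, rec, minorityStrideS = 16, targetRatio = 1)
  # labels of pre-existing windows unchanged
  expect_equal(windowLabels(bal)[seq_along(before)], before)
  # added windows are seizure-labelled and within the span
  added <- seq(nWindows(ws) + 1, nWindows(bal))
  expect_true(all(windowLabels(bal)[added] == 1L))
  expect_true(all(windowStarts(bal)[added] >= 192 &
                  windowStarts(bal)[added] + 64 <= 392))
  # provenance: every added window equals the source slice at its offset
  for (i in added) {
    i0 <- round(windowStarts(bal)[i] * fs) + 1
    expect_identical(getWindow(bal, i), unname(sig[, i0:(i0 + 64 * fs - 1)]))
  }
  # the 200-s span supports at most floor((200-64)/16)+1 = 9 distinct windows
  expect_lte(sum(windowStarts(bal) >= 192 & windowStarts(bal) + 64 <= 392), 9)
})

test_that("balancing is the identity when disabled, already balanced, or unannotated", {
  fs <- 32
  sig <- matrix(rnorm(640 * fs), 1, dimnames = list("A", NULL))
  rec <- EEGRecording(sig, fs,
                      annotations = data.frame(start = 192, end = 392,
                                               label = "seizure"))
  ws <- labelWindows(segmentWindows(rec, 64, 64), annotations(rec))
  expect_identical(balanceByOverlap(ws, rec, targetRatio = 0), ws)
  recNoAnn <- EEGRecording(sig, fs)
  expect_warning(out <- balanceByOverlap(ws, recNoAnn), "no seizure annotations")
  expect_identical(out, ws)
})
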