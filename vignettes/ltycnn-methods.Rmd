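---
title: "Seizure detection with multiscale convolution and attention: methods and design notes"
author: "ltycnn"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Seizure detection with multiscale convolution and attention}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ltycnn)
```

# The problem

Epileptic seizures appear in scalp EEG as episodes of high-amplitude,
rhythmic, low-frequency activity that is synchronized across many channels,
against a background of broadband 1/f activity, alpha/beta oscillations and
powerline contamination. `ltycnn` implements a complete detection pipeline
for this setting: a reproducible synthetic EEG simulator, EDF input/output,
preprocessing, time-frequency feature extraction with PCA, and a lightweight
classifier (LTY-CNN) that combines parallel multiscale convolution, a
quantization-aware dilated convolution, and multihead self-attention. The
unit of classification is a 64-second, 18-channel analysis window at
256 Hz (16,384 samples per channel), labelled ictal (1) or interictal (0).

# The synthetic data generator

Every downstream stage is testable without downloading clinical data
because the simulator produces annotated recordings with a controlled
ground truth. Per channel the background is

* 1/f-shaped Gaussian noise (power slope −1, shaped in the frequency
  domain; components below 0.5 Hz are suppressed so the background does
  not drift), default variance 600 µV²;
* an amplitude-modulated alpha oscillation at a random frequency in
  8–12 Hz (default variance 200 µV²) and a weaker beta oscillation in
  18–25 Hz, each with per-channel random phase;
* powerline sinusoids at 60 Hz (8 µV amplitude) and 120 Hz (4 µV) with
  random phase. These produce a spectral peak ≥ 10 dB above neighbouring
  bins — deliberately, since removing them is the preprocessing contract.

The combined background RMS is ≈ 30 µV, a physiologically plausible scalp
amplitude that also fixes the EDF physical scaling. Each ictal episode adds
a rhythmic spike-wave-like waveform: a sinusoid at the ictal fundamental
(default 3 Hz, the classic spike-wave band) plus its second and third
harmonics with exponentially decaying amplitudes (1, e⁻¹, e⁻²), normalized
to unit RMS and scaled to `ictalAmplitudeGain` times the background RMS.
The waveform is phase-locked across a random subset of at least half the
channels — this creates the strong inter-channel correlation structure that
distinguishes ictal from background epochs — and is ramped on and off with
1-second cosine tapers. Episode intervals are placed by rejection sampling
with guard margins (8 s, shrunk adaptively for short recordings) and are
pairwise disjoint, half-open `[start, end)` in seconds.

What the simulator does **not** emulate: clinically realistic ictal
electrography (evolution of frequency and morphology over the seizure),
artifacts (EMG, eye blinks, electrode pops), inter-subject variability, or
non-stationary background. A classifier that separates this synthetic task
perfectly has therefore demonstrated that the pipeline is wired correctly
and can learn band-limited, spatially coherent rhythmic structure — not
that it reaches clinical performance on real data.

```{r}
cfg <- synthConfig(duration = 768, nSeizures = 2, ictalAmplitudeGain = 6,
                   seed = 1)
rec <- simulateRecording(cfg)
writeDataset(list(rec), "dataset/")
```

# Preprocessing

* **Resampling.** Recordings are downsampled to 256 Hz. Integer ratios
  (512 → 256, 1024 → 256, the rates of the public datasets this pipeline
  is modelled on) use FIR polyphase decimation; other ratios use a rational
  polyphase resampler. Upsampling is refused as out of regime. In testing,
  FIR decimation preserved a 5 Hz tone's amplitude to ~0.1%, while the
  generic rational resampler showed ~2.5% ripple — hence the integer path.
* **Powerline removal.** Band-stop 4th-order Butterworth sections at
  57–63 Hz and 117–123 Hz, applied forward-backward (zero phase). The
  realized response attenuates 60 and 120 Hz by more than 40 dB and leaves
  10 and 100 Hz within 1 dB of unity. The first-order transfer-function
  sketches that motivate these bands are treated as response *contracts*;
  they are not realizable discrete filters as written.
* **High-pass.** 4th-order Butterworth at 1 Hz, forward-backward, followed
  by removal of the residual mean: the forward-backward pass leaves a small
  boundary-transient DC offset (~10⁻³ relative), and the explicit demeaning
  makes the DC rejection exact by construction.
* **Windowing.** Half-open windows of 64 s, starts at `0, stride, …` while
  `start + 64 ≤ duration`, 0-based, times in seconds. A window is labelled
  ictal when ≥ 50% of it overlaps an annotated seizure; windows with
  nonzero overlap below 50% are ambiguous and dropped by default (they can
  be kept as either class). Mixed windows corrupt both classes, so
  exclusion is the default.
* **Class balancing.** Seizures are rare, so the ictal class is
  oversampled by cutting additional windows from inside annotated seizure
  spans at a 16-s stride (75% overlap at the 64-s window) until the classes
  are balanced or the spans are exhausted. Background windows are never
  duplicated; every added window records its source and start time, and
  existing windows and labels are never altered.

# Features

* **Spectrogram.** Per channel, a magnitude STFT with 1-s (256-sample)
  Hann segments and 50% overlap (128-sample hop), one-sided, followed by
  `log(1 + magnitude)` compression. On a 16,384-sample window this gives
  `floor((16384 − 256)/128) + 1 = 127` time frames at 1 Hz resolution;
  retaining bins from 1 Hz (the high-pass cutoff) to 114 Hz (below the
  117 Hz stop-band edge) gives 114 bins. This is the unique natural STFT
  configuration that reproduces the reference 127 × 114 grid, and the
  log(1+·) compression stabilizes the dynamic range.
* **PCA.** Each of the 127 frames is flattened over (channel, frequency)
  into an 18 × 114 = 2052-dim vector; the frame population is mean-centred
  and decomposed as `X = U D Vᵀ`; the first k = 64 right singular vectors
  form the projection `Y = X W`. The choice k = 64 makes the PCA output
  dimension coincide with the attention embedding width, giving a coherent
  end-to-end tensor flow (127-step sequence of 64-dim features per window).
  The implementation uses the eigendecomposition of the smaller Gram
  matrix, which is algebraically equivalent to the SVD and is verified
  against a full `svd()` oracle in the tests; a direct dense SVD of a
  fold-level frame matrix costs tens of seconds on one core for no
  numerical benefit. The basis is always fitted on training frames only;
  cross-validation refits it inside every fold, and the retained
  cumulative explained-variance ratio at k = 64 is reported per fold
  rather than used for automatic k selection.
* **Channel correlation.** Pearson correlation between the 18 channel
  time series, the standard view of ictal spatial synchronization. A
  zero-variance channel yields zeros in its row/column with a warning (the
  diagonal stays 1) rather than NaNs.

# The classifier

The input is the 127 × 64 feature sequence. Layers, in order:

1. **Parallel multiscale branches.** Three 1-D convolutions with kernels
   7 / 5 / 3 ("wide / medium / narrow") and 4 output channels each act on
   the *same* input and their ReLU-activated outputs are concatenated:
   `F_total = Concat[Act(F_wide), Act(F_medium), Act(F_narrow)]`,
   12 channels × 127 steps. The branches are mutually independent
   computations; the parallel form is about architecture (each branch sees
   a different temporal scale), and no wall-clock claim is attached to it.
2. **Quantization-aware dilated convolution.** Kernel 3, dilation d = 2
   (receptive field `R = k + (k−1)(d−1) = 5`), projecting 12 → 64
   channels. Both the incoming activations and the kernel are quantized to
   n = 8 bits with the uniform quantizer
   `Q(x) = Δ · floor(x/Δ + 1/2)`, `Δ = 2 max|x| / 2ⁿ` (per tensor,
   recomputed each forward pass; Δ ≡ 1 with Q ≡ 0 on an all-zero tensor so
   silent windows cannot divide by zero). Quantization is simulated in
   floating point (fake quantization); integer-only inference kernels are
   out of scope. Only this layer is quantized — it is the layer the
   quantized-convolution formulation pairs with — and all other layers are
   full precision.
3. **Layer normalization** over the 64 features of each time step.
4. **Multihead self-attention** over the 127-step axis: 4 heads on a
   64-dim stream, d_k = 16 per head,
   `Attention(Q,K,V) = softmax(QKᵀ/√d_k) V`, heads concatenated and
   projected by `W^O`. A note on width: the published description sets the
   per-head embedding to 64 with 4 heads, which would concatenate to 256
   and cannot meet the published 24,506-parameter budget; the standard
   convention (total width 64 split across heads) is used instead, and
   this discrepancy is documented rather than hidden.
5. **Mean pooling** over time and a **linear 2-class head**.

No residual connections are used; the published description names the
blocks but not a skip topology, and the network is shallow enough that
optimization does not need them. The reference instantiation has exactly
23,118 trainable parameters (closed-form accounting and brute-force
enumeration agree), within the 24,506 budget.

## Training

Softmax cross-entropy minimized with Adam (learning rate 10⁻³, batch 32,
default 30 epochs), seeded and single-threaded for reproducibility.
Sequences are divided by the training-set standard deviation (stored in the
model) before the forward pass; this single scalar keeps the PCA scores in
a range where the random-init network is well conditioned without touching
the per-component structure. The quantizers stay active in the forward
pass and are bypassed with straight-through (identity) gradients in the
backward pass: the true derivative of the quantization staircase is zero
almost everywhere, so the printed gradient-of-expected-error sketch is
realized as the standard straight-through estimator, which is what
quantization-aware training means in practice. The entire backward pass is
hand-derived and was verified against central finite differences
(agreement ≤ 2×10⁻⁷ relative per block; the quantized layers were checked
with a fine quantization grid because the straight-through surrogate
intentionally disagrees with the staircase's pointwise derivative).

## Evaluation

`computeMetrics` reports TP/TN/FP/FN and Acc/Sen/Spe exactly per their
defining ratios, with zero-denominator cases flagged as undefined (NaN)
rather than silently zeroed. `rocAuc` sweeps all score thresholds with
ties grouped and integrates trapezoidally; this equals the Mann–Whitney
concordance probability with ties counted 1/2, and the tests assert
equality against a brute-force pairwise oracle to 10⁻⁹. `kfoldSplit`
provides stratified window-level folds (default, mirroring a window-level
protocol) and recording-grouped folds (`groupByRecording = TRUE`,
recommended against within-recording leakage on real data — the published
protocol does not state its unit of splitting, so both are provided).
Stratified assignment rotates leftover windows across classes so total
fold sizes differ by at most 1 while per-fold class counts stay within 1.
`evaluateCV` recomputes the PCA basis inside each training fold, never
touching held-out frames.

# Problem sizes and numerical choices

* The packaged synthetic dataset (`syntheticSeizureWindows()`) uses 10
  recordings × 768 s, two seizures of 96–160 s each, gain 6, yielding 66
  background and 66 seizure windows — comfortably above 40 per class so
  that 5-fold stratified splits keep ≥ 13 windows of each class per fold.
* End-to-end cross-validation runs (tests and examples) train 15 epochs:
  on this separable task the loss plateaus well before that, and the runs
  stay desk-scale on a single core.
* Per-fold PCA fitting subsamples at most 3,000 training frames
  (seeded); with ~13,000 frames per fold the basis estimate is already
  stable, and the Gram-matrix eigendecomposition of a 2052² matrix
  dominates the cost otherwise.
* Softmax rows are computed max-shifted; layer norm uses ε = 10⁻⁵; "same"
  zero padding everywhere; odd kernels keep padding symmetric (enforced by
  the configuration validity check).
* EDF files are written with one-second records, symmetric physical range,
  fixed header date, so identical configurations give byte-identical
  files and the roundtrip error is bounded by (physical range)/2¹⁶.

# Known limitations

* The synthetic ictal model is deliberately simple; see above for what
  passing tests do and do not establish about clinical data.
* The "heuristic overlapping sampling" for class balance is realized as
  the fixed-stride overlap oversampler described here; the published name
  has no published specification.
* Detection, not forecasting: windows are labelled by overlap with the
  annotated seizure interval itself. A preictal-horizon labelling option
  is deliberately not enabled by default because the published task
  definition does not resolve detection versus early prediction.
* `trainModel` is single-threaded, pure R; it is sized for the packaged
  problem (thousands of windows), not for training on full clinical
  archives.
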