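Package: ltycnn
Title: Lightweight Multiscale Convolution and Attention Pipeline for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting epileptic seizures in
    multichannel scalp EEG. Provides a reproducible synthetic EEG simulator
    with annotated ictal episodes, EDF reading and writing with JSON
    annotation sidecars, preprocessing (anti-aliased resampling to 256 Hz,
    zero-phase powerline band-stop and 1 Hz high-pass filtering, 64-s
    windowing with overlap-based class balancing), time-frequency feature
    extraction (short-time Fourier spectrograms reduced to 64 principal
    components), and a lightweight classifier (LTY-CNN) combining parallel
    multiscale convolution branches, a quantization-aware dilated
    convolution, and multihead self-attention, trained with straight-through
    gradients and evaluated by stratified k-fold cross-validation with
    accuracy, sensitivity, specificity, ROC and AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
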