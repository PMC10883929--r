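Package: ecghvit
Title: Hybrid ResNet-Vision-Transformer Localization of Myocardial
    Infarction from 12-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for myocardial infarction detection and
    localization from 12-lead electrocardiograms. Provides Daubechies-6
    wavelet denoising, Pan-Tompkins QRS detection, fixed-window beat
    segmentation, a "slim" multibranch convolutional patch-embedding stem
    with squeeze-and-excitation channel attention, a reduced-depth vision
    transformer encoder, a residual-network feature branch, concatenation
    feature fusion with a dense prediction head, and a stratified k-fold
    evaluation harness with per-class metrics, confusion matrices and ROC
    curves. Includes a class-conditional synthetic 12-lead ECG generator
    with known R-peak ground truth so the whole pipeline is testable
    without clinical data. Neural layers are implemented natively on top
    of R matrix algebra with reverse-mode gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
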