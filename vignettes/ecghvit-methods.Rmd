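---
title: "Hybrid ResNet-ViT myocardial infarction localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ResNet-ViT myocardial infarction localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myocardial infarction (MI) leaves territory-specific fingerprints on the
12-lead ECG: ST-segment elevation or depression, pathological Q waves and
R-wave changes on the leads facing (or reciprocal to) the infarcted wall.
`ecghvit` implements an end-to-end pipeline that localizes an infarct to
one of eleven wall territories (plus healthy control) from single-beat
12-lead images: wavelet denoising, Pan-Tompkins beat detection,
fixed-window segmentation, and a two-branch deep classifier that fuses a
residual convolutional network with a vision transformer whose patch
embedding is produced by a multibranch convolutional stem with channel
attention.

Because clinical ECG archives cannot ship with a package, every stage is
exercised against a synthetic class-conditional 12-lead generator with
known ground truth. The generator is first-class, tested code: it defines
the study conditions under which the pipeline's properties are verified.

## Pre-processing

**Denoising.** Signals are decomposed with the periodized orthogonal
discrete wavelet transform using the Daubechies-6 basis. The transform is
implemented in-package (circular convolution with the analysis pair,
dyadic downsampling), is exactly invertible, and was verified against an
independent reference implementation; the reference coefficients are
frozen in the test suite. The decomposition depth defaults to
`min(4, maximum permitted by the signal length)` and detail bands are
soft-thresholded at the universal threshold $\sigma\sqrt{2\ln N}$ with
$\sigma$ the median absolute deviation of the finest detail band over
0.6745 — the standard ECG wavelet-shrinkage recipe. Setting
`detail_levels = integer(0)` disables shrinkage and makes the round trip
an identity, which the tests exploit. Denoising never changes signal
length.

**Beat detection.** R peaks are found with the Pan-Tompkins cascade:
band-pass (Butterworth order 3, 5–15 Hz, zero-phase), five-point
derivative, squaring, 150 ms moving-window integration, then adaptive
dual-threshold selection with running signal/noise estimates (update
weights 0.125, search-back at 0.5 of the primary threshold when an RR gap
exceeds 1.66 times the running average, 200 ms refractory period, and a
0.36 s/half-height T-wave discrimination rule). These are the canonical published constants for the detector; every one
is exposed in `peak_config()`. Detection runs on a single
configurable lead (II by default, where R waves are conventionally
largest); segmentation then slices all leads at the detected indices.
Detected integration peaks are snapped to the local maximum of the input
signal within ±75 ms so the returned indices point at R waves of the
signal itself.

**Segmentation.** Each beat spans 250 samples before the R peak and 400
after (651 total), the fixed window the classifier is built around. Beats whose
window crosses a record edge are dropped by default; `"pad-edge"`
replicates the boundary sample instead. At the generator's default
360 Hz this window is about 0.69 s before / 1.11 s after the R peak; records at other
sampling rates can be polyphase-resampled (`resample_record()`) to keep the sample-count window
physically consistent.

**Window selection.** The integration-window width trades missed QRS
complexes against T-wave interference. `optimize_window()` instantiates
the cost $C(W) = \text{miss} + \text{false} + \lambda\,\text{twave}$
(the T-wave term being the fraction of detections closer to an annotated
T apex than to any true R peak), evaluates it on annotated records over a
candidate grid, and reports the minimiser with ties broken toward the
smaller width, together with the dimensionless constant $k = W f_s$ of
the closed form $W = k/f_s$.

## The classifier

**Slim patch-embedding stem.** The standard ViT embeds an image by one
16×16 convolution. Here that is replaced by four multibranch stages, each
computing

$$O(x) = F_{s=2}(x) + L_{s=2}(x), \qquad
  H(x) = \mathrm{SE}\!\left[F_{s=1}(O) + L_{s=1}(O) + O\right],$$

with $F$ a 3×3 and $L$ a 1×1 convolution (each followed by batch
normalization and ReLU, the conventional conv-BN-ReLU ordering) and SE the
squeeze-and-excitation gate: global average pool, bottleneck dense pair
(reduction 16 by default, the customary ratio),
sigmoid, channelwise rescale. Stage widths are 48/96/192/384 and a final
1×1 convolution expands to 768 channels, so a 224×224 input leaves the
stem as a 14×14×768 embedding map — spatial size halves exactly once per
stage. Odd-sized stage inputs are rejected rather than padded to keep
that contract exact. Where the stage's identity addition must change
width, the stride-2 branches carry the width change so the sum is always
well-formed.

**Encoder.** The 14×14 grid is flattened row-major into 196 tokens, a
learned classification token is prepended, and learned positional
embeddings are added. The encoder is the de-facto-standard pre-norm
ViT block (LayerNorm → multi-head self-attention → residual, LayerNorm →
GELU MLP → residual) at a depth of exactly two less than the reference
model. ViT-Base (12 layers, 12 heads, MLP ratio 4) is taken as the
reference, giving depth 10; head count and MLP width follow that
reference since the depth reduction alone defines the modification. The classification token attends but is
excluded from the feature path: the last layer's remaining hidden states
are flattened token-major and mapped by one dense layer
($F = W_f\,\mathrm{flatten}(H) + b_f$) to exactly the residual branch's
feature width. That parity is enforced at construction, not checked at
run time.

**Residual branch.** Basic residual blocks
$H_i = H_{i-1} + F(H_{i-1})$ (projection shortcut on width or stride
changes; no activation after the addition, so zeroing $F$ is exactly the
identity) over a stem of one 3×3 stride-1 convolution with 64 filters,
batch norm (momentum 0.1, epsilon 1e-5), ReLU and a 3×3 stride-2 max
pool — deliberately not the canonical 7×7 stem, keeping early spatial
detail for thin ECG traces. Network depth is configurable: the default is the 18-layer basic-block layout
(feature width 512) with a 50-layer bottleneck option (width 2048), and
arbitrary reduced layouts via `blocks_per_stage`/`stage_channels`. The
classification layer is removed structurally: features are the global
average pool, and nothing after the pool changes dimensionality. The
package ships no pretrained weights, so branches initialise randomly;
`load_checkpoint()` loads externally trained weights and
`freeze_resnet` supports staged training.

**Fusion and training.** The two feature vectors (equal halves) are
concatenated and passed through one 256-unit ReLU dense layer with
dropout 0.35 (the midpoint of the conventional 0.2–0.5 range) and a softmax
over the 12 classes; `hidden_sizes` generalises the head to deeper dense
stacks. Training is joint
end-to-end with Adam at learning rate 0.001, decoupled
weight decay 1e-4 on weight matrices, categorical cross-entropy, batch
32. Every random choice (initialisation, shuffling, dropout) derives
from the recorded seed, so runs are bit-reproducible.

All neural layers are implemented natively in R on BLAS matrix algebra
with hand-written reverse-mode gradients (im2col convolutions,
channel-major `[C, H, W, N]` layout so normalisation and activations are
reshape-free). Every layer and the full fused model are verified against
finite-difference gradients in the test suite.

## Evaluation

`compute_metrics()` scores each class one-vs-rest — accuracy
$(TP+TN)/N$, precision, recall/sensitivity, F1, specificity
$TN/(TN+FP)$, $FPR = 1-\text{specificity}$, $FNR = 1-\text{sensitivity}$
— plus macro averages, the confusion matrix in counts and row-percent
views, and per-class ROC curves by threshold sweep with trapezoidal AUC
(cross-checked against an independent implementation in the tests).
`kfold_evaluate()` runs the 10-fold protocol: stratified folds (per-class
round-robin after a seeded shuffle, so per-fold class counts are within
one of proportionality), a freshly initialised model per fold, and a
class × fold table of one-vs-rest accuracies alongside the per-fold
reports. Macro averaging is used for aggregates so small classes weigh equally; argmax ties break toward the lower class index.

## The synthetic generator

Beats are sums of five Gaussian bumps (P, Q, R, S, T) with conventional
amplitudes, latencies and widths, repeated at 75 bpm with seeded RR
jitter (sd 0.02 s), projected onto the 12 leads by fixed per-lead gains
(aVR inverted), at 360 Hz by default. Class signatures superimpose:

- a smooth ST plateau (raised-cosine shoulders, 60–240 ms after R) of
  ±0.2 mV on the leads facing each territory,
- pathological Q waves (40% of the lead's R amplitude, 60 ms width) on
  the classes defined by them,
- tall R in V1–V2 for posterior involvement,
- reciprocal ST depression for the inferior-territory classes.

The anterior class is modelled as ST depression with Q waves across
V1–V6; the anteroseptal class carries Q waves in V2–V3 together with the
textbook ST elevation V1–V3, so that every class is separable in the ST
feature space — a property the probe invariant below requires. The
remaining classes follow the standard territory patterns. White Gaussian noise is added
per lead at a configurable SNR; the clean reference, true R-peak and
T-apex indices are stored, making detection and segmentation scoreable
against ground truth.

Rendering is deterministic anti-aliased drawing: 12 stacked lanes in
canonical lead order (or a 4×3 panel grid), dark trace on white, fixed
±1.8 mV amplitude scale per lane so absolute ST displacement survives as
a sub-pixel intensity shift rather than being normalised away.

**What passing on synthetic data shows — and what it does not.** The
generator produces stationary, template-based beats with white noise
only: no baseline wander, electrode artefacts, rhythm disorders,
inter-patient morphology variation, or class overlap. Passing the
end-to-end criteria therefore demonstrates that the architecture is
wired correctly, that gradients flow end-to-end, and that the pipeline
can extract lead-localised ST/Q signatures from rendered beats — not
that the printed clinical accuracies transfer; those require the
external datasets and full-scale training.

## Desk-scale configuration and numerical choices

The full-scale model (224 px, 768-dim, depth-10 encoder, ResNet-18
branch) is instantiated for the architecture contracts; training runs use
`build_reduced_model()`: 48×48 grayscale input, slim channels
4/8/16/32 → 32, encoder reference depth 4 (built depth 2, 2 heads, MLP
ratio 2), residual stages 8/16 (feature width 16), 32-unit fusion layer.
The 10-fold harness trains 12 epochs per fold on 12 classes × 20 beat
images; the two-class overfit check uses 30 epochs on 40 images. These
sizes were fixed from single-fold pilot runs (held-out accuracy reaches
0.96–1.0 from epoch 7 at 48 px) before the acceptance checks were run.

Numerical details: softmax rows are max-shifted before exponentiation;
cross-entropy clamps probabilities at 1e-12; batch-norm uses biased batch
variance with an unbiased running update (momentum 0.1); the universal
threshold uses the MAD/0.6745 scale estimate; ROC tie groups keep the
last point per threshold; `optimize_window()` breaks cost ties toward
the smaller window; non-finite encoder activations or training losses
abort with a diagnostic rather than propagate.

## Known limitations

- CPU-only, interpreter-bound training: practical at the reduced scale;
  the full-scale model forward-passes in seconds but is not trainable at
  realistic dataset sizes in R.
- The WFDB reader covers formats 16 and 212 only.
- The synthetic generator is not a physiological simulator (single
  morphology family, no rhythm disorders, white noise only).
- No attention-map explainability or saliency tooling.
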