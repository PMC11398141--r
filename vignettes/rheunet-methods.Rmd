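---
title: "Liver and tumor CT segmentation with rheunet: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver and tumor CT segmentation with rheunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheunet)
```

## The problem and the model

Automatic delineation of the liver and of liver tumors in abdominal CT is
hampered by low lesion contrast (hypodense tumors sit only a few tens of
Hounsfield units below liver parenchyma), large anatomical variability, and
small lesion sizes. `rheunet` implements RHEU-Net, a U-Net-style
encoder-decoder that addresses these difficulties with three components:

1. **Residual modules** in place of U-Net's plain double convolutions.
   Each module first maps its input to the stage width with a conv1 unit
   (3×3 convolution, batch normalisation, activation), computes a residual
   branch through a three-segment sequence (conv1, conv1, conv2 — the conv2
   unit omits the activation so the branch enters the addition un-rectified,
   as in ResNet), adds the branch to the first unit's output
   (`H(x) = F(x) + x`), and finishes with another conv1 unit. Encoder
   modules activate with ReLU; decoder modules use ELU (α = 1), whose
   non-saturating negative tail helps detail reconstruction.

2. **Hybrid Gated Attention (HGA)** on every skip connection. The encoder
   feature map `F` is processed by two parallel attention streams —
   channel attention `FC = F · σ(W2 δ(W1 AvgPool(F)))` (a
   squeeze-and-excitation bottleneck with reduction ratio `r`) and spatial
   attention `FS = F · σ(Conv7×7(cat(mean_c F, max_c F)))` — and the two are
   fused per pixel by a learned gate
   `g = σ(Conv1×1(δ(Conv1×1(cat(FC, FS)))))`, a single-channel map in (0,1):
   `F_out = (1 − g)·FC + g·FS`. The output is therefore an elementwise
   convex combination of the two attention streams; the final gate
   convolution is zero-initialised so an untrained gate blends both streams
   equally (g = 0.5).

3. **Multi-Scale Feature Enhancement (MSFE)** at the bottleneck: an
   atrous-spatial-pyramid block with five parallel branches — a 1×1
   convolution, three 3×3 *depthwise-separable* dilated convolutions at
   rates 4, 8 and 12, and a global-average-pooling branch — concatenated and
   fused by a 1×1 convolution + batch norm + ReLU. A global-context
   reweighting then computes a per-channel attention map
   `a = σ(δ(BN(Conv1×1(GAP(x)))))` and returns `x·a + x` (attention-weighted
   features plus an additive skip), followed by a final 1×1 projection.
   With a 3×3 kernel at dilation 12 a single tap spans
   `3 + 2·11 = 25` pixels, so the deepest features see receptive fields far
   beyond the plain bottleneck's.

The segmentation head is a 1×1 convolution to two channels with independent
sigmoids — liver and tumor are treated as a multi-label problem, matching
the binary compound loss below; tumor overrides liver in composite label
maps because lesions lie inside the organ.

## Loss

Training minimises `BCEDiceLoss = α·BCE + (1 − α)·Dice` with α = 0.5:

* `DiceLoss = 1 − (2Σ y·x + ε) / (Σ y + Σ x + ε)` with ε = 1e−5, computed
  per channel and batch item and averaged with equal weight, so the rare
  tumor class is not swamped by the liver class;
* `BCELoss = −mean(y log x + (1−y) log(1−x))` with probabilities clipped to
  `[1e−7, 1 − 1e−7]`.

Dice alone destabilises training when both the target region and the
prediction are small (the denominator is tiny and gradients explode); the
BCE term supplies well-scaled pixel-wise gradients in exactly that regime,
which is why the compound loss is used.

## Input pipeline

CT volumes are windowed to the soft-tissue range `[−60, 140]` HU
(width 200, level 40), min-max scaled to [0, 1] **against those fixed
bounds** (not per-volume extremes, so intensities are comparable across
volumes), and contrast-equalised per slice with CLAHE (clip limit 2,
8×8 tiles, via EBImage). We apply CLAHE after the normalisation so it always
operates on a fixed [0, 1] domain; the alternative order is a free choice
since the sources describe the steps but not their composition. The network
input is 2.5D: the target slice stacked with its two neighbours as three
channels (edge slices replicate), against the two binary masks of the centre
slice (liver = label ≥ 1, tumor = label 2). Augmentation applies a random
crop (480 px at full scale, 96 px at desk scale), horizontal/vertical flips
and ±90° quarter turns — the rotation angle is realised as quarter turns
since those are exact on the pixel grid — identically to image and masks.

## Training

Adam (β = 0.9/0.999) with decoupled L2 weight decay 1e−5 on convolution
weights, batch size 4, initial learning rate 1e−4 decaying exponentially by
0.95 per epoch, dropout 0.2 after the bottleneck and the two deepest decoder
stages. The optimiser is a choice: the sources specify the learning-rate
schedule and L2 regularisation but not the optimiser; Adam is the standard
companion of a 1e−4 initial rate. Validation runs every epoch on up to three
largest-liver slices per validation volume (a cheap but stable proxy), and
the state with the best mean of liver and tumor Dice is restored at the end.
Slices without liver are mostly excluded from training (a configurable 10%
of them is kept) to limit trivially negative samples.

## Synthetic phantoms

Real annotated abdominal CT cannot ship with the package, so the
`phantom_spec()`/`generate_phantom()` module draws desk-scale CT-like
volumes: a randomly posed (shifted, scaled, in-plane rotated) liver
ellipsoid at 60 ± 10 HU on a −100 HU background, containing 0–3 ellipsoidal
hypodense lesions at 20 ± 10 HU placed strictly inside the liver mask by
bounded rejection sampling, plus 5 HU of global Gaussian noise. Defaults are
12 slices of 96 × 96 at 1 × 1 × 5 mm spacing; liver in-plane semi-axes
20–30 px and through-plane 2.5–3.5 slices give liver fractions of roughly
5–10% of the volume and five to seven liver-bearing slices — a miniature of
the segmentation geometry, scaled to the 96-px training crop. The intensity
defaults straddle the soft-tissue window so windowing is non-trivial, and
the hypodense ordering mirrors the typical portal-venous appearance of
lesions (a `hyperdense` flag exists for the opposite regime).

Phantoms emulate the *mechanics* of the task — contrast relations,
windowing, class imbalance, 3D context, empty slices — but not anatomy:
no organ-shaped boundaries, vessels, texture, or breathing artifacts.
Passing the synthetic end-to-end checks therefore demonstrates that the
implementation learns and segments under the stated conditions, not that it
reproduces clinical benchmark accuracy.

## Numerical design

The environment provides no deep-learning framework, so the package carries
its own small CNN engine. Feature maps are R arrays with dim
`c(H, W, N, C)`; with column-major storage every (image, channel) plane is
contiguous, which the C++ kernels exploit. Convolutions are computed as
GEMMs: the fused conv+BN+activation unit used throughout the residual
blocks evaluates a 3×3 convolution as nine BLAS GEMMs on shifted views of a
zero-padded buffer (no im2col materialisation; out-of-range contributions
land in padding that is never read), and caches the padded input and the
normalised pre-activation between the forward and backward pass of a
training step. General convolutions (dilated, depthwise, 7×7) use an
im2col path, 1×1 convolutions multiply the channel matrix directly, and the
tiny 2-channel 7×7 spatial-attention kernel uses a direct loop. A
single-precision GEMM path (`options(rheunet.single_precision = TRUE)`, the
training default) roughly halves step time; all accuracy-sensitive
computations and tests use the double-precision default. Batch-norm uses
biased batch variance for normalisation, unbiased updates for the running
statistics (momentum 0.1, ε = 1e−5). Weights are Kaiming-initialised
(fan-in, gain for ReLU on both ReLU and ELU paths) from the configuration
seed, so a configuration reproduces its weights exactly. Backward passes
are hand-derived per module and verified against central finite differences
in the test suite; the first encoder convolution skips its input gradient.

Degenerate inputs: max pooling requires even spatial dims (the network
checks divisibility by `2^depth` up front and names the required multiple);
MSFE warns once when the bottleneck is smaller than 13 px (the rate-12
branch then sees mostly padding) but still computes; CLAHE passes constant
slices through unchanged; metric ratios with empty truth and empty
prediction score 1, empty truth against a non-empty prediction scores 0
(common liver-benchmark practice).

## Open choices and their resolutions

* **Channel attention pooling** — the governing equation uses average
  pooling only; a shared-bottleneck average+max variant exists behind
  `use_max_channel` (default off, the equation wins).
* **Gate width** — "reduce the channels by half" of the 2C concatenation is
  read as width C; `gate_width` overrides.
* **MSFE reweighting target** — the attention map reweights the fused map by
  default; `reweight_pre_fusion = TRUE` reweights the 5-branch concatenation
  instead (the textual description is ambiguous).
* **Residual segment order** — the three-segment branch is conv1, conv1,
  conv2 with the addition taken after conv2, the only reading under which
  "the output of conv1 is added to the output of conv2" type-checks and the
  addition happens before an activation, as in ResNet.
* **Bottleneck widths for MSFE** — branch and output widths equal the
  bottleneck width (base·16), with the pooled encoder output (base·8)
  entering, so MSFE is a drop-in replacement for the widening double
  convolution.
* **Aggregation of evaluation metrics** — per-case (volume) means by
  default, with pixel-pooled aggregation available (`mode = "pooled"`);
  benchmark tables in this field do not state their scheme.

## Problem sizes used by the shipped checks

Unit tests run on miniature tensors (≤ 16 px, ≤ 8 channels) against naive
direct-convolution oracles and finite differences. The end-to-end check
trains the full model (base width 8) on 200 phantom volumes (8:2
volume-level split, 10 epochs, batch 4, 96-px crops, seed 0) and requires
held-out per-volume mean Dice of at least 85% (liver) and 50% (tumor);
`scripts/acceptance.R` runs a reduced profile by default (140 volumes,
about 14 minutes) and reproduces the full-size conditions with
`--volumes 200`. The tumor class is learned late in training at these
scales, so held-out tumor Dice depends steeply on the dataset size and
step count; liver Dice saturates early. These sizes are the package's desk-scale study
conditions; the full-scale profile of the method (480-px crops, 120 epochs,
base width 64) is exposed by the same functions but is not exercised by the
automated checks.

## Limitations

* The phantom generator is a mechanism test bed, not an anatomy simulator;
  reported synthetic Dice values say nothing quantitative about clinical
  data.
* The engine targets a single CPU; there is no GPU or multi-core path.
* Only 2D (2.5D-input) segmentation is implemented; no 3D convolutions,
  deep supervision, or test-time augmentation.
* Checkpoints are R serialisations of the weight state; they are
  reproducible across sessions but not interchangeable with other
  frameworks.
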