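---
title: "Super-resolving plant images: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolving plant images: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantsr)
```

## The problem

Object-detection and counting models for plant imagery (seed counting,
fruit counting) degrade sharply when their inputs lose resolution. Single
image super-resolution (SR) reconstructs a plausible high-resolution (HR)
image $I_{SR}$ from a low-resolution (LR) input $I_{LR}$, and can serve as
a preprocessing step for such pipelines: upscale first, detect second, and
rescale any pixel-distance parameters of the detector's post-processing by
the same factor ([`scaleDistanceCutoff()`]). This package implements the
PlantSR network family, the lightweight reference networks it is compared
against (SRCNN, VDSR, EDSR), the bicubic degradation operator that
synthesizes LR training inputs, the evaluation metrics, a patch-based
training loop with transfer-learning support, tiled full-image inference,
and a deterministic synthetic-image generator so that the whole pipeline is
testable from a clean checkout.

## The model

PlantSR is a post-upsampling residual network operating at LR spatial size
until a final pixel-shuffle reconstruction:

* **Shallow features.** A single 3x3 convolution maps RGB to $C$ feature
  channels: $F_0 = H_{SF_0}(I_{LR})$. A stack of $m$ residual groups
  refines it: $F_1 = H_{SF_1}(F_0)$.
* **Deep features.** A stack of $n$ further residual groups produces
  $F_{DF} = H_{DF}(F_1)$.
* **Reconstruction.** $I_{SR} = H_{UP}(F_0 + F_1 + F_{DF})$, where
  $H_{UP}$ is a 3x3 convolution expanding to $C s^2$ channels, a pixel
  shuffle by the scale $s$, and a 3x3 convolution back to RGB.

Each residual group is four *Residual SE-attention Blocks* (RSEBs)
followed by a 3x3 convolution, plus a skip connection from the group
input. An RSEB computes $x + SE(\mathrm{conv}(\mathrm{relu}(
\mathrm{conv}(x))))$ with squeeze-and-excitation channel attention:
global average pooling to a $C$-vector, a bottleneck $C \to C/r \to C$
gating network, a sigmoid, and channel-wise rescaling.

Two design points deserve explanation:

* **The group-level trailing convolution.** With a bare skip
  ($RG(u) = \mathrm{blocks}(u) + u$) a group whose blocks are identities
  would double its input rather than pass it through. Ending the group
  with a convolution before the skip (the convention of channel-attention
  SR networks) makes a zero-weight group exactly the identity, which is
  also the property the test suite asserts: zeroing all group convolutions
  reduces the network to $H_{UP}(3 F_0)$.
* **Residual-aware initialization.** He-style initialization applied
  naively to a stack of additive skip connections grows activation
  variance linearly with depth; with twelve blocks and the three-way
  feature fusion the initial outputs leave the unit range and early
  optimization is wasted rescaling them. The package therefore
  zero-initializes every group's trailing convolution (groups start as
  identities), scales the He draw of the in-block and head convolutions by
  0.1, and mean-shifts inputs by $-0.5$. These are standard stabilizations
  for residual SR stacks, and parameter counts are unaffected.

The depth presets (`PlantSRConfig`) are $C = 64$, $r = 16$, $m = 2$ and
$n = 4, 8, 12$ for scales 2, 3, 4: the per-scale parameter budget then
grows steeply with scale, mirroring the published budgets qualitatively.
The exact published hyper-parameters are not printed in the source
material, so the package does not claim to reproduce the PlantSR parameter
counts; the configuration is fully exposed instead.

## Reference networks

The three lightweight comparison networks are rebuilt exactly, validated
by their published parameter budgets (in millions, three decimals):

| network | construction | parameters |
|---|---|---|
| SRCNN | 9x9 conv 3->64, 5x5 conv 64->32, 5x5 conv 32->3, on the bicubic-upscaled input | 69,251 = 0.069 M |
| VDSR | twenty bias-free 3x3 convs at 64 channels with a global residual from the bicubic-upscaled input | 667,008 = 0.667 M |
| EDSR | 16 residual blocks at 64 channels, global skip, pixel-shuffle tail | 1,369,859 / 1,554,499 / 1,517,571 (x2 / x3 / x4) |

VDSR's published budget of 0.667 M is only reproduced by the bias-free
construction used in its well-known public implementation (an all-bias RGB
build gives 668,227, which rounds to 0.668); the package follows the
bias-free convention. SRCNN and VDSR operate on all three RGB channels —
the luminance-only variants would not match the published budgets.

## Degradation operator

LR inputs are synthesized, and the classical baseline computed, with a
separable Keys bicubic kernel ($a = -0.5$), center-aligned coordinate
mapping (output pixel $i$ samples input coordinate $(i - 0.5)/\mathrm{zoom}
+ 0.5$, 1-based), edge replication, per-pixel weight normalization, and —
when downsampling — kernel dilation by the zoom factor (antialiasing).
This is the convention of Matlab's `imresize`, the de-facto standard for
SR benchmarks; the source material does not state its resize convention,
so the `antialias` flag is exposed for sensitivity checks. HR images are
cropped at the top-left corner to a multiple of the scale before
downsampling. The implementation is validated against a dense 2-D
kernel-summation oracle to 1e-9.

## Metrics

* **PSNR** $= 10 \log_{10}(MAX^2 / MSE)$ with $MAX = 255$, computed
  jointly over RGB on 8-bit values, no border cropping (the source
  formula fixes $MAX = 255$ and mentions neither luminance conversion nor
  border shaving). Identical images report `Inf`.
* **SSIM** with $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$, $L = 255$. The
  default estimator is the field-standard 11x11 Gaussian window
  ($\sigma = 1.5$), per channel, averaged over the valid interior. A
  `"global"` mode evaluates the printed single-statistics formula once per
  channel; it is the literal transcription used by the oracle tests.
* **MAE / RMSE** over per-image object counts, for scoring counting
  pipelines from a `image_id,y_true,y_pred` CSV.

Whether published table values were computed on full test images or on
fixed-size crops is ambiguous in the source; both paths exist
(`evaluateModel()` on full images, patch-level evaluation via
`extractPatch()` + `psnr()`).

## Training protocol

`trainSR()` follows the published settings: 32 patches per batch of
64 px HR side (63 px at scale 3 so the patch divides by the scale),
horizontal-flip augmentation, L1 pixel loss in unit-float space, Adam at
`lr0 = 1e-4` (β = 0.9/0.999, ε = 1e-8; the source states only the
optimizer and the initial rate — the learning-rate halving schedule it
mentions belongs to the out-of-scope counting detector, so no decay is
applied here). Patches are sampled uniformly over images then positions,
with replacement, from whole-image degraded LR/HR pairs so patch
statistics match full-image inference. Each epoch ends with a full-image
PSNR/SSIM evaluation; the best-PSNR epoch (earliest on ties) is retained —
best-epoch checkpointing per the published protocol. `batchesPerEpoch` is
configurable: the published 38,997 batches per epoch is specific to the
830-image corpus, while the synthetic experiments here use tens of
batches. `fineTuneSR()` restarts training from a checkpoint and records
the parent checkpoint as provenance; it is the transfer-learning entry
point used to specialize a model to close-up imagery of one crop.

All sampling is driven by a single seed; a re-seeded run reproduces the
batch stream bit-for-bit.

## Synthetic data

`genPlantTexture()` emulates the statistical structure the method needs:
band-limited fine texture (random sinusoidal gratings up to 0.45
cycles/px with mild 1/f amplitude decay), sharp venation-like ridge
lines, smooth illumination, and a green- or brown-dominant palette. The
tests assert that more than 1% of spectral power lies above half the
Nyquist frequency of the 2x-downsampled grid — the regime bicubic
interpolation cannot recover, so the SR task is non-degenerate.
`genCountingScene()` adds non-overlapping shaded disks with known centers
for the counting harness. What the generator does **not** emulate:
photographic noise, optics, JPEG artifacts, or real botanical morphology.
Tests passing on these fixtures demonstrate the pipeline's correctness,
not field performance on real plant photographs.

## Problem sizes and the small-scale training experiment

The repository's experiments are sized for a single CPU: the overfit
smoke experiment trains the small configuration ($C = 16$, $m = 1$,
$n = 2$, $r = 4$, scale 2; about 116k parameters) for 200 Adam steps of
32 patches on 8 procedural 96x96 images (seed 0) and compares its
full-image PSNR on those images against bicubic upscaling. Two hundred
steps is very early in an SR training trajectory — published training
runs take tens of thousands of batches per epoch — so this experiment
checks that optimization moves the network in the right direction at
meaningful speed, not that it reaches trained quality. Trained-model
quality figures from the source material (e.g. 40+ dB at scale 2 on the
real corpus) require GPU-scale training on the real dataset and are out
of scope; the package's acceptance surface replaces them with exact
parameter counts, metric closed forms, oracle equivalences and the
architecture contracts.

## Numerical choices and degenerate inputs

* uint8 -> unit-float conversion divides by 255 exactly; the reverse
  rounds half away from zero then clamps, making the round trip the
  identity on all 256 values.
* Bicubic weights are renormalized to sum to one at every output pixel,
  so constant images are preserved exactly at any size.
* `psnr()` returns `Inf` for identical images rather than erroring.
* SSIM's windowed mode refuses images smaller than the window; the global
  mode handles any size, including constant images (stabilized by
  $C_1, C_2$).
* Tiled inference averages overlapping tile outputs; with the default
  16 px overlap the interior agrees with the untiled forward pass to
  1e-5, and single-tile plans short-circuit to the direct pass.
* A patch request outside the image raises an error — no implicit
  padding anywhere in the data path.
* Networks reject non-RGB inputs; grayscale files are promoted to RGB at
  decode time instead.

## Known limitations

* No RAW/TIFF/multispectral support; PNG and JPEG only, with PNG used for
  every lossless intermediate.
* The training loop is single-threaded CPU code built on BLAS matrix
  kernels; it is meant for small-scale experiments, fine-tuning and
  testing, not for reproducing GPU-scale training runs.
* Only bicubic degradation is modelled (no blur/noise/compression
  pipelines).
* The counting detectors themselves are out of scope: the package
  produces their upscaled inputs and scores their count outputs.
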