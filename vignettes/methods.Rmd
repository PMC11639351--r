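---
title: "Hybrid Transformer-CNN tumour segmentation: model, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Transformer-CNN tumour segmentation: model, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tctnet)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
phantoms do and do not emulate, the numerical choices, and the design
decisions taken where the architecture description left something open.

## The problem and the model

Gliomas are segmented from multi-modal 3D MRI into nested regions — whole
tumour (WT), tumour core (TC), enhancing tumour (ET) — against an extreme
class imbalance: tumour tissue is typically well under 5% of the brain and a
fraction of a percent of the scan. The network here combines a convolutional
inductive bias (locality, translation equivariance) with transformer
self-attention (global context, dynamic weighting) in a four-stage U-shape.

**Encoder.** The stem is a 7×7×7 convolution with stride 2 and padding 3
followed by layer normalisation and GELU. Wide-kernel strided stems model
within-patch structure that plain patch embedding discards, and — because the
convolutions themselves carry positional information — the transformer blocks
need *no positional encoding*; the permutation-equivariance of the attention
path absent such encoding is asserted in the tests. Stages run at 1/2, 1/4,
1/8, 1/16 of the input resolution, connected by 2×2×2 stride-2 convolutional
patch embeddings, with block depths (2, 2, 2, 4) and heads (2, 4, 8, 16).

Inside each block, queries keep the full token sequence while keys and values
are produced by a *convolutional projection*: reshape the tokens to their 3D
grid, apply a depth-wise convolution of stride `k` (the per-stage reduction
rates are 8, 4, 2, 1), flatten back, and apply learned pointwise projections.
Self-attention is then `Softmax(QKᵀ/√d_k)V` per head with `d_k = C/n`. The
K/V sequence shrinks by `k³`, which is what keeps 3D attention affordable:
with this resolution ladder, `scale × k = 16` at every stage, so the K/V grid
is always (input side / 16)³ (8³ for a 128³ crop) — the schedule is internally
coherent only for this ladder, which is why the stem feeds stage 1 directly at
1/2 resolution.

**Decoder.** Each decoder scale upsamples by a transposed convolution
(kernel 2, stride 2), fuses the concatenated skip features through a residual
block (two 3×3×3 conv + layer-norm + GELU with a pointwise shortcut), and
refines with a **3D direction-wise convolution block**: six sub-paths, one per
permutation of the X/Y/Z axes, each applying three uni-directional depth-wise
convolutions (kernels a×1×1, 1×a×1, 1×1×a), fused by concatenation, projected
back to the block width, layer-normalised, added to the input and passed
through GELU. Long thin kernels decompose a large receptive field by
direction, which suits irregular, spiculated tumour boundaries. A fourth
direction-wise block operates at the original scale — on upsampled features
only; there is deliberately no full-resolution encoder path, whose memory cost
is the reason such paths are avoided in 3D — before the 1×1×1 softmax head.

**Loss.** For probabilities `P` and targets `G` over `I` voxels and `C`
classes,

$$L = -\tfrac1I \sum_{i,c} G_{ic}\log P_{ic} \;+\; 1 -
\tfrac2C \sum_c \frac{\sum_i G_{ic}P_{ic}}{\sum_i G_{ic}^2 + \sum_i P_{ic}^2 + \varepsilon},$$

i.e. voxel-mean cross-entropy plus one minus the mean soft-dice fraction; at a
perfect prediction each class fraction reaches 1/2 and the loss vanishes (up
to ε). The dice term is what gives minority classes leverage against the
background.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `stage_widths` | 60/120/240/480 | channel widths; the one free capacity knob, calibrated once (below) |
| `stage_depths` | 2/2/2/4 | transformer blocks per stage (reference schedule) |
| `stage_heads` | 2/4/8/16 | attention heads; must divide widths |
| `stage_reductions` | 8/4/2/1 | K/V depth-wise stride per stage |
| `mlp_ratio` | 4 | vanilla-transformer MLP expansion |
| `dw_kernel_length` | 7 voxels | uni-directional kernel length a (odd) |
| `lr` | 1e-4 | AdamW initial rate, cosine-annealed over the epochs |
| `epochs` / `finetune_epochs` | 300 / 200 | reference budgets; desk-scale runs use far fewer |
| `patch_size` | 128³ voxels | training crop = inference ROI |
| `crop_mix` | 0.5 | fraction of label-guided crops (1:1 mix) |
| overlap | 0.5 | sliding-window overlap fraction |
| `sigma_scale` | 0.125 of ROI | Gaussian importance width, floored at 1e-3 of peak |
| `eps` | 1e-5 | dice smoothing |

**Width calibration.** The architecture description fixes depths, heads and
reductions but not the channel widths; its only quantitative capacity
constraint is the 640-GFlops forward-pass budget at a 4-channel 128³ input.
The widths were therefore calibrated once: over a grid of stem widths in
multiples of 4 (40–96, doubling per stage, heads dividing widths), stem 60
minimises |total − 640| at 665.7 GFlops (+4.0%). The counter uses the
multiply-add = 2 convention and ignores normalisation/activation/softmax
terms; because the convention of the printed budget is unstated, reports also
carry the multiply-add = 1 total (332.9). `measureFlops()` re-counts from the
shapes actually executed during a real forward pass and agrees with the
analytic walk, which the tests pin to 5%.

## Design decisions where the description was open

* **K/V projection kernel.** Only the stride `k` is given. Implemented as
  kernel `k`, stride `k` (non-overlapping) for `k > 1`, and kernel 3,
  stride 1, pad 1 for `k = 1`, so a centred delta kernel is exactly the
  identity. K and V use two separate depth-wise convolutions (whether they
  share one is unstated; separate is the general reading).
* **Head handling.** The description can be read as repeating the reduced K/V
  `n` times per head; standard head-splitting (`d_k = C/n`) is implemented
  instead, since the `√d_k` scaling presupposes it and repetition would make
  heads identical.
* **Learned Q/K/V projections.** The projection equations show no pointwise
  weights; they are applied anyway because multi-head mixing requires per-head
  learned sub-spaces.
* **Patch embedding.** 2×2×2 stride-2 non-overlapping convolution + layer
  norm — the simplest reading of "convolutional patch embedding".
* **Output head.** Four exclusive classes (background + 3 tissues) under one
  softmax, with WT/TC/ET derived afterwards; training directly on the three
  overlapping region channels under a softmax is available via
  `regionTargetChannels()` but is not the default, because overlapping targets
  contradict a softmax's mutual exclusivity.
* **Upsampling.** Transposed convolution, kernel 2 stride 2 (learnable,
  standard in 3D U-shapes; the description is silent).
* **Sub-path widths.** Each direction-wise sub-path maps C → C and the 6C
  concatenation is projected back to C, avoiding divisibility-by-6
  constraints.
* **Normalisation "foreground".** Strictly nonzero voxels (skull-stripped
  inputs have exact-zero background).
* **Rotations.** Restricted to multiples of 90° so labels move as pure
  permutations and need no interpolation.
* **Gradient clipping.** Global norm 1.0, protecting the batch-size-1 regime.
* **Blending space.** Sliding-window blending happens in probability space
  (after softmax); logit-space blending would weight confident windows
  differently and the description does not distinguish them.
* **Fine-tuning.** All four encoder stages are the "deep layers" kept when
  transferring to a new dataset; any parameter whose shape matches is copied,
  and the stem/head are re-initialised when channel counts differ.

## The synthetic phantoms

`generatePhantom()` emulates the *structure* of multi-modal brain tumour
data: a large healthy-tissue ellipsoid (nonzero intensity, label 0) on an
exact-zero background; axis-aligned ellipsoidal lesions with concentric
labels — edema shell (2), necrotic/non-enhancing ring (1), enhancing core (4),
so ET ⊆ TC ⊆ WT by construction; four channels with modality-like contrast
patterns (edema bright on the FLAIR/T2 analogues, necrosis dark on T1,
enhancing core bright on T1gd); a per-voxel anatomical texture shared across
channels; and Gaussian noise. Ellipsoids keep region volumes analytically
checkable; a fixed seed makes every phantom bit-reproducible.

Two design constraints matter more than they look:

1. **Percentile stability.** Intensities are normalised per channel to [0, 1]
   by the 5th/95th percentiles of the foreground. If the healthy tissue were
   homogeneous, that band would be a few noise standard deviations wide and
   every lesion contrast would clip to exactly 0 or 1 — and, worse, the p95
   would jump between healthy tail and lesion range depending on lesion size,
   making the intensity-to-class mapping inconsistent *across* cases. The
   shared texture (uniform ±0.35) gives the foreground a wide, distribution-
   stable percentile band, as real brain tissue has, and lesion contrasts (≤
   0.13) sit inside it.
2. **Foreground fraction.** The healthy ellipsoid is large (0.48 of each axis)
   so the lesion stays a small fraction of the *foreground*, again keeping the
   percentiles case-stable.

What the phantoms do **not** emulate: real anatomy and spatially correlated
texture, partial-volume boundaries, bias fields and multi-site intensity
shifts, MRI physics/noise structure, and multifocal irregular lesion shapes
(a `warp`-style deformation is deliberately out of scope; ellipsoids keep the
volume arithmetic exact). Passing the desk-scale tests therefore shows the
*machinery* is correct — shapes, gradients, blending, sampling, optimisation —
and that the pipeline can learn a consistent multi-channel contrast mapping;
it does not certify segmentation quality on clinical data, and the published
BraTS Dice scores are not reproducible here (they need the real dataset and
multi-GPU training budgets).

## Numerical choices

* Exact GELU (`x·Φ(x)`) everywhere; layer norm over the channel axis with
  ε = 1e-5.
* Weight init: truncated normal (σ = 0.02, ±2σ) for projections and
  convolutions, unit gains and zero biases for norms; all draws under the
  config seed, so two models built from the same config are bit-identical.
* Loss: `log` clamped at P ≥ 1e-7; dice ε = 1e-5; classes absent from a patch
  are dropped from the dice mean by default (`include_empty_classes = FALSE`),
  because an absent class contributes 0/ε and would otherwise deflate the
  objective on lesion-free patches.
* Sliding windows: stride `max(1, round(roi·(1−overlap)))`, final window
  clamped flush to the boundary; Gaussian map peak-normalised and floored at
  1e-3 so no voxel has zero weight; per-voxel weights cancel in the
  normalisation, so outputs remain on the simplex to 1e-6.
* Volumes smaller than the ROI are symmetrically zero-padded and cropped back.
* Ties in the argmax label decoding resolve to the lowest class index
  (`which.max`), i.e. background on a perfect tie.
* Double precision throughout; two forward passes with identical weights and
  inputs are bit-identical, and training under a fixed seed reproduces the
  loss trajectory exactly.

## Desk-scale study sizes

The test suite exercises everything on a single CPU with a small
configuration (stem 8, widths 8/16/32/64, head 4; ~450k parameters):

* *Overfit capacity check*: one 32³ phantom (lesion radii 6–8), 450
  optimisation steps at constant lr 2e-3 without augmentation reaches WT
  Dice ≥ 0.93 on the trained phantom — the standard check that the
  architecture plus hand-derived gradients can drive the loss to a solution.
* *Generalisation smoke test*: 8 training phantoms at 48³ (lesion radii
  8–11, WT ≈ 3–4% of the volume), 32³ crops in the 1:1 random/label-guided
  mix, 240 steps; 20 held-out 48×48×64 phantoms are segmented by sliding
  windows. Held-out WT Dice ≈ 0.87 with the full scheme.
* *Inference-mode ranking*: on those 20 held-out phantoms the three modes
  rank, on average, no-overlap ≤ overlap 0.5 ≤ overlap + Gaussian
  (WT 0.78 / 0.81 / 0.87 for the briefly trained model above). The ranking is
  a stochastic property: the test asserts each adjacent step with a 0.02
  tolerance and the end-to-end gain strictly. For a *converged* model on
  these smooth phantoms the Gaussian step becomes neutral-to-slightly
  negative — boundary-uncertain predictions are where central-voxel
  confidence weighting pays, which matches its motivation; the exact
  reference ablation numbers require the real dataset.
* *Crop-ratio experiment*: 10 default phantoms (one ~0.2%-volume lesion in
  128³), 10 random + 10 label-guided crops each at half the volume side; the
  mean patch tumour ratio exceeds the whole-volume ratio for WT, TC and ET —
  the class-imbalance mechanism of label-guided cropping. Uniform random
  crops alone preserve the expected ratio; the guided half concentrates the
  lesion (≈ 8× here), so the printed 1:1 mix roughly quadruples tumour
  exposure.
* Training smoke tests use 16³ phantoms, where a forward/backward pass costs
  ~0.1 s.

These sizes are the package's own desk-scale choices; the training loop, loss
and inference code paths are identical at full scale, only the configuration
grows.

## Known limitations

* CPU-only and single-threaded by design: a full-scale 300-epoch run on real
  data is out of scope for this implementation; the value is inspectability
  and testability of every component.
* No deep supervision, attention gates, test-time augmentation or model
  ensembling.
* The five-fold cross-validation harness is a thin wrapper around the
  training entry points rather than a tuned benchmarking rig; the validation
  split is a fixed-seed 80/20 by case.
* Only 90°-multiple rotations are implemented (labels stay interpolation-free);
  arbitrary-angle rotation would require label resampling rules the
  reference description does not give.
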