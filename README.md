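# tctnet

Volumetric tumour segmentation with a hybrid Transformer–CNN network, in pure
R (plus small C++ kernels for the 3D convolutions). The package implements the
full method end to end — network, loss, patch sampling, training loop,
sliding-window inference — together with an analytic compute-cost model and a
synthetic phantom generator, so everything is exercisable on a desktop CPU
with no external data.

## Who this is for

Researchers in medical image analysis who want a dependency-light, fully
inspectable reference implementation of a modern 3D segmentation
architecture: every forward pass, every hand-derived gradient, and every
blending rule is ordinary R code that can be read, unit-tested and modified.

## The model

The network is a four-stage U-shaped encoder–decoder for multi-channel 3D
volumes (e.g. 4-modality brain MRI):

* **Encoder.** A stem block (7×7×7 convolution, stride 2, padding 3, layer
  norm + GELU) feeds stage 1 at 1/2 resolution; 2×2×2 stride-2 convolutional
  patch embeddings sit between stages, giving scales 1/2, 1/4, 1/8, 1/16 with
  depths (2, 2, 2, 4) and heads (2, 4, 8, 16). Each block is a pre-norm
  transformer whose keys and values come from a *convolutional projection*:
  tokens are reshaped to their 3D grid, reduced by a stride-`k` depth-wise
  convolution (reduction rates 8, 4, 2, 1 per stage, so the K/V grid is
  input/16 per axis at every stage), flattened, and linearly projected.
  Attention is standard scaled dot-product per head,
  `Softmax(QKᵀ/√d_k)V` with `d_k = C/n`; there is **no positional encoding**.
* **Decoder.** At each scale a transposed convolution (kernel 2, stride 2)
  upsamples, a residual block fuses the concatenated skip features, and a
  **3D direction-wise convolution block** refines them: 6 sub-paths, one per
  permutation of the X/Y/Z axes, each applying three uni-directional
  depth-wise convolutions (a×1×1, 1×a×1, 1×1×a with a = 7), fused by
  concatenation, pointwise projection, layer norm, a residual connection and
  GELU. One more direction-wise block operates at the original scale before a
  1×1×1 softmax head.
* **Loss.** Soft dice + cross-entropy per voxel over `C` exclusive classes:
  `L = −(1/I)ΣᵢΣ_c G log P + 1 − (2/C)Σ_c (Σ G·P)/(Σ G² + Σ P² + ε)`.
* **Training.** Patch-based (crops of the inference ROI) with a 1:1 mix of
  uniform-random and label-guided crops against class imbalance, AdamW with a
  cosine-annealed learning rate (reference defaults: 300 epochs, batch 1,
  lr 1e-4), flips/rotations and intensity augmentation.
* **Inference.** Sliding windows with overlap 0.5 blended under a Gaussian
  importance map (σ = 0.125·ROI, peak-normalised, floored at 1e-3), so central
  voxels with full context dominate the blend.

Evaluation uses the Dice similarity coefficient `2|A∩B|/(|A|+|B|)` on the
three nested tumour regions WT ⊇ TC ⊇ ET derived from the exclusive labels
(BraTS convention: WT = {1,2,4}, TC = {1,4}, ET = {4}).

## Worked example

```r
library(tctnet)

# a small BraTS-like phantom family: 4 channels, nested lesion, ~97% background
spec <- phantomSpec(shape = c(48, 48, 48), lesion_radius_range = c(8, 11), seed = 100)
cases <- lapply(1:8, function(i) { s <- spec; s$seed <- spec$seed + i; generatePhantom(s) })

model <- tctnet(modelConfig(in_channels = 4, n_classes = 4, stem_width = 8,
                            stage_widths = c(8, 16, 32, 64), head_width = 4, seed = 7))
fit <- trainModel(model, cases,
                  trainConfig(epochs = 30, lr = 2e-3, schedule = "constant",
                              patch_size = 32, augment = NULL, seed = 5))

held <- generatePhantom(phantomSpec(shape = c(48, 48, 64),
                                    lesion_radius_range = c(8, 11), seed = 501))
probs <- slidingWindowInfer(normaliseIntensity(held$image), fit$final_model,
                            roi = 32, overlap = 0.5, use_gaussian = TRUE)
ev <- evaluateSegmentation(list(labelsFromProbs(probs)), list(held$labels))
print(ev)
#>       case        WT TC ET
#> 1 case_001 0.8717949  0  0
```

The row reports held-out Dice overlap between predicted and true nested
regions: 87% of the whole-tumour mask is recovered by a ~450k-parameter
network after only 240 CPU optimisation steps (about four minutes). The inner
regions are still at zero at this budget — whole tumour is learned first, and
separating core from enhancing core needs several times more steps (the
package's overfit test reaches TC 0.99 / ET 0.93 on a single phantom at 450
steps).

The compute-cost model prints where the flops go:

```r
show(countFlops(modelConfig(), c(4, 128, 128, 128)))
#> FlopReport for input 4x128x128x128
#>   total: 665.7 GFlops (one multiply-add = 2 flops; norm/activation/softmax ignored)
#>   total: 332.9 GFlops under multiply-add = 1
#> ...per-layer table...
```

The published configuration (stage widths 60/120/240/480) was calibrated once
so this total lands on the 640-GFlops forward-pass budget of the reference
design: over a grid of stem widths in multiples of 4 with per-stage doubling,
stem 60 minimises the distance to the budget (+4.0%). `measureFlops()` runs an
instrumented forward pass as an independent cross-check of the analytic count.

There is also a thin command-line surface in `inst/cli/tctnet.R`
(`make-phantoms`, `train`, `finetune`, `infer`, `evaluate`, `flops`).

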