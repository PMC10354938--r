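---
title: "Methods: parallel CNN-transformer segmentation with masked axial attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel CNN-transformer segmentation with masked axial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axialseg)
```

This vignette is the package's account of its model, the choices made where
the design was genuinely open, and what the desk-scale experiments do and
do not show.

## The model

The network is U-shaped. Its distinguishing ideas are three:

1. **A parallel encoder.** Each encoder unit runs a transformer branch and
   a bottleneck-residual convolution stage *side by side on the same
   input*, rather than replacing convolutions with attention. The
   convolution branch owns local texture; the transformer branch owns
   long-range context.

2. **Distance-masked axial attention.** The transformer branch pools the
   token grid to one profile per axis (`fH[i] = mean over j`,
   `fW[j] = mean over i`), projects them with shared query/key maps, and
   forms per-axis, per-head correlation matrices. Each correlation entry is
   multiplied by a distance mask that equals 1 on the diagonal and beyond a
   cutoff `a`, and `k d^2 - k a^2 + 1` at distance `0 < d < a` — strongly
   negative near the diagonal at the default `k = 0.5`, so short-range
   attention is actively suppressed rather than merely down-weighted. The
   two axes are reconnected as a separable product: the joint logit between
   tokens `(i, j)` and `(i', j')` is
   `(mask * corrH)[i, i'] x (mask * corrW)[j, j']`, realized as a
   Kronecker product in row-major token order. Values are computed from the
   full (unpooled) token sequence; pooling the value path would collapse
   the output to rank one per axis.

3. **Gated fusion (GLF).** The transformer stream emits a spatial gate
   (channel mean/max pooling, 7x7 convolution, sigmoid) and a channel gate
   (global average pooling, two-layer bottleneck MLP, sigmoid); both gate
   the convolution stream elementwise before each stream is compressed by a
   1x1 convolution, concatenated, and fused by a 3x3 convolution.

The composite objective is `0.5 BCE + 0.3 Dice + 0.2 Ohem(edge)`: the edge
term supervises an auxiliary 1x1 head against the Canny edge of the ground
truth mask, keeping only the hardest pixels because the edge band is a tiny
minority class.

## Design choices where the design was open

These points are places where the architecture description alone does not
pin down an implementation; the package commits to one reading and exposes
the alternative as configuration where reasonable.

- **Normalization of masked logits.** The axial correlation/mask algebra
  does not itself define a normalization. Because the surrounding block is
  standard multi-head self-attention, the package applies the usual
  `1/sqrt(headDim)` scaling and a softmax over keys *after* the mask
  multiplies the raw correlations. Applying the mask to raw (pre-softmax)
  correlations means a negative mask value flips the sign of a negative
  correlation into a large positive logit; `attentionConfig(clampMask =
  TRUE)` clamps mask values at 0 for users who want to rule that out. The
  default keeps the mask exactly as defined.
- **Discontinuity at the diagonal.** At distance 1 the mask value is
  `1 + k - k a^2` (strongly negative for the defaults) while the diagonal
  itself is exactly 1 — a discontinuity, since a token's self-attention is
  never suppressed. The mask is implemented exactly as defined; the
  self-attention spike is arguably the intent (a token may always attend
  to itself).
- **No positional embeddings.** The encoder adds no learned positional
  code: position enters through the parallel convolution branch and the
  distance mask itself. This is a deliberate reading, kept as the default.
- **Q/K sharing.** The same query/key projections serve both axes (the
  axial profiles live in the same channel space), and the value/output
  projections act on full tokens.
- **Stem split.** The five-stage residual backbone contributes its first
  two stages (plus the 7x7 stem convolution and pool) to the shared stem,
  and stages 3-4 to the convolution branches of units 1-2. "Former part"
  readings differ; two stages in the stem keeps both units genuinely
  parallel.
- **Transformer-branch downsampling.** Each unit's transformer branch
  enters at half resolution via 2x2 average pooling followed by a 1x1
  projection, so both branches land on the same extent for fusion. The
  downsampling mechanism is otherwise unconstrained; average pooling is
  the least-parameter choice consistent with the axial mean pooling used
  inside the attention.
- **Edge head.** Edge probabilities come from a dedicated 1x1 head on the
  final decoder feature. `networkConfig(edgeFromGradient = TRUE)` instead
  derives them from the spatial gradient magnitude of the segmentation
  probabilities — useful when the edge supervision should not add
  parameters — but the dedicated head is the default and trains better in
  the desk-scale experiments.
- **GLF pooling axes.** For the spatial gate, pooling must run over the
  channel axis (pooling over space would collapse the map it is supposed
  to produce); for the channel gate, over space. The package follows the
  convolutional-block-attention convention the module is modelled on.
- **Dice numerator.** The Dice loss keeps the conventional factor 2 in the
  numerator so a perfect prediction attains loss 0; `lossConfig(diceFactorTwo
  = FALSE)` reproduces the raw form (optimum 0.5) for strict comparison.
  Losses are mean-reduced per pixel for batch-size-independent learning
  rates; a sum reduction is available.
- **Ohem keep rule.** "Keep the hardest pixels" is made concrete as
  `max(ohemMinKept, ceiling(keepFraction * n))` pixels per image (defaults
  0.25 and 256), selected per image, ties broken by pixel index so results
  are deterministic.
- **Canny thresholds.** Hysteresis thresholds default to 10/100 on the
  0-255 gradient scale — a deliberately wide range so mask boundaries are
  always captured — and the edge band is dilated by 1 px so the
  supervision is not a one-pixel hairline.
- **Best-model selection.** The checkpoint with the best validation mDice
  is retained; that metric also drives the 8:1:1 train/validation/test
  protocol of the command-line interface.

## The compute core

No deep-learning framework backs this package: it ships a small
reverse-mode autodiff engine (`R/autodiff.R`) whose tensors are dense
arrays in `[H, W, C, N]` layout, plus analytic backward passes for every
layer. Convolutions run through compiled im2col + GEMM kernels
(`src/conv.cpp`); everything else is BLAS-backed R. Every backward pass is
validated against central finite differences in the test suite, and the
attention path against dense loop oracles. Determinism: evaluation-mode
forward passes are pure functions of parameters and input; training is
reproducible because all randomness (generator, initialization, shuffling,
augmentation) is seeded, computation is single-threaded, and batch-norm
running statistics update deterministically.

Numerical details worth knowing:

- BCE and Ohem losses are computed in logit space
  (`max(z,0) - z y + log1p(exp(-|z|))`) to avoid overflow; the
  probability-space functions clip at `1e-7`.
- Batch normalization uses biased variance in the normalization and
  unbiased variance in the running estimate (momentum 0.1).
- Bilinear resampling uses half-pixel centre alignment; masks always use
  nearest-neighbour so they stay binary.
- Max-pool ties resolve to the first kernel tap in row-major order.

## The synthetic data regime

`genSample` emulates the lesion-segmentation regime the architecture
targets: each image holds 1-3 star-convex blobs (elliptical base radius
modulated by a low-order random harmonic series), filled with an intensity
offset of `contrast = 0.35` from a textured background, boundary-blurred
with `sigma = 1.5` px and overlaid with pixel noise (`sd = 0.06`). These
defaults were chosen once as a realistic desk-scale stand-in for
low-contrast, fuzzy-edged lesions: hard enough that an untrained network
scores near zero and a trained one visibly benefits from context, easy
enough that a width-16 network learns it in minutes on one CPU.

What the generator does *not* emulate: specular highlights, instrument
occlusion, non-lesion distractor structures, colour distribution shifts
between acquisition devices, and annotation noise. Passing the packaged
experiments therefore demonstrates that the architecture, losses and
training loop are implemented correctly and can learn this class of
shape-from-texture segmentation — not that the network reaches any
particular accuracy on clinical data.

## Desk-scale experiment sizes

The packaged experiments (`overfitExperiment`, `generalizationExperiment`)
use the 64x64, width-16 configuration (`tinyNetworkConfig()`): stem width
16, stages of one bottleneck block each, two masked-axial blocks per
encoder unit, a depth-4 bottleneck, 2 heads, decoder widths
128/64/48/32/16. The overfit check runs 200 full-batch steps on 8 fixed
samples without augmentation; the generalization run trains on 200
generated samples with the full augmentation suite for 10 epochs at batch
8 — exactly one cosine cycle (restart period 10, multiplier 2), so the
learning rate anneals to its floor by the final epoch — and evaluates the
best-validation parameters on 50 unseen samples.
These sizes are the package's reference conditions; the same code paths
scale to the 512x512 width-64 configuration unchanged.

## Known limitations

- Binary segmentation only (one sigmoid channel); the benchmark tasks this
  architecture family targets are all foreground/background.
- The joint attention matrix is materialized per head; at 512x512 input
  the first unit's 1024-token grid costs ~8 MB per head per image, which
  is fine at these depths but would not scale to much finer token grids.
- Batch normalization at batch 4-8 is noisy by nature; the small-batch
  regime matches the training protocol but group normalization might
  behave better and is not implemented.
- No pretrained backbone weights: the checkpoint interface can load a
  serialized parameter tree, but all packaged experiments start from
  random initialization.
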