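---
title: "Methods: a residual-dense-attention U-Net for liver and lesion CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a residual-dense-attention U-Net for liver and lesion CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hepatocellular carcinoma is usually assessed on abdominal CT. Delineating
the liver and its lesions slice by slice is slow and error-prone,
particularly on non-contrast scans where lesion boundaries are faint. This
package implements an automatic segmentation pipeline around an
encoder-decoder convolutional network: CT slices go in, per-pixel
probability maps and binary masks for the liver (or the lesions) come out,
and a four-metric protocol scores the result against expert ground truth.

Everything runs on a single CPU. The network layers, their gradients and
the Adam optimizer are implemented inside the package (with compiled C++
for the convolution patch extraction), so there is no dependency on an
external deep-learning framework; this keeps the full pipeline — data,
model, training, evaluation — testable end to end in a plain R session.

## The model

The architecture is a U-Net whose encoder stages combine two ideas and
whose decoder gates its skip connections:

* **Residual blocks.** Each stage first applies `H(x) = F(x) + x`, where
  `F` is two 3×3 convolution → batch-norm → ReLU stages and the shortcut is
  the identity (or a 1×1 convolution when the channel count changes).
  Writing the stage as a residual keeps gradients flowing through deep
  encoders: a stage can fall back to (near-)identity, so added depth cannot
  easily make things worse.
* **Dense blocks.** After the residual block, a densely connected block
  runs `dense_layers` convolutions, each consuming the concatenation of the
  block input and all previous outputs and emitting `growth_rate` new
  channels. Feature reuse through concatenation keeps the per-layer width
  small while giving later layers direct access to earlier features; the
  block's output has `in + layers × growth` channels, an arithmetic
  identity the tests assert numerically.
* **Attention gates.** Each decoder stage gates the corresponding encoder
  skip feature with the coarser decoder signal one level below: both are
  projected by 1×1 convolutions into an intermediate space (the skip after
  a strided 1×1 downsampling, since the gating signal has half its spatial
  size), summed, passed through ReLU, projected to one channel, and
  squashed by a sigmoid into per-pixel coefficients in (0, 1). The
  coefficients are upsampled (nearest-neighbour, exact ×2) and multiplied
  into the skip, suppressing regions the decoder considers irrelevant. In
  the saturation limits the gate becomes a pass-through (coefficients → 1)
  or full suppression (→ 0); both limits are asserted to 10⁻⁶.

Downsampling is 2×2 max pooling; upsampling is a learned 2×2 stride-2
transposed convolution; gated skip and upsampled path are concatenated and
fused by two 3×3 convolutions; the head is a 1×1 convolution plus sigmoid,
so the output is a one-channel probability map at input resolution.

### Hyperparameters and defaults

`arch_config()` collects everything the architecture diagram leaves open:

| parameter | default | meaning |
|---|---|---|
| `input_size` | 224 px | network grid; must be divisible by `2^depth` |
| `depth` | 4 | encoder resolution levels (plus bottleneck) |
| `base_filters` | 16 | channels at the top level, doubling per level |
| `dense_layers` | 4 | convolutions per dense block |
| `growth_rate` | half the level width | channels added per dense layer |
| `attention_inter_channels` | half the skip channels | gate bottleneck width |
| `norm` | `"batchnorm"` | per-convolution normalization (`"none"` available) |
| `blocks` | `"serial"` | residual block then dense block per encoder stage |

Design choices that were genuinely open, and the package's resolution:

* **Serial composition.** The encoder stage applies the residual block and
  then the dense block. Alternative compositions are exposed through
  `blocks = "res_only"` / `"dense_only"` for ablations.
* **Channel schedule.** Widths, dense depth and growth rates are not fixed
  by the architecture description; the defaults above land the default
  configuration at roughly 6.5 million parameters (reported by
  `count_parameters()`, which the tests tie to an independent per-layer
  hand summation). The published parameter total of the original
  architecture depends on filter widths that are only shown in a diagram,
  so no specific total is treated as a reproduction target; any
  configuration can be frozen to YAML via the command-line interface.
* **Gate plumbing.** The gated skip is concatenated with the upsampled
  decoder path (the standard additive-attention U-Net layout); the gate's
  internal downsampling of the skip is a learned strided 1×1 convolution,
  and the coefficient upsampling is nearest-neighbour so the ×2 resampling
  is exact and cheaply differentiable.
* **Normalization.** Batch normalization after each convolution (running
  statistics for inference); the residual identity property holds exactly
  in both modes because freshly initialized batch norm is an odd function
  at zero.
* **Loss.** Pixelwise binary cross-entropy by default, with soft Dice and
  BCE+Dice available (`train_config(loss = ...)`). Gradients are taken with
  respect to the pre-sigmoid logits, which keeps BCE numerically stable.
  For the lesion target — foreground covering well under 1% of pixels —
  plain BCE pushes a briefly trained model toward the empty prediction, so
  the desk-scale lesion experiment uses the Dice-augmented loss
  (`"bce_dice"`), the standard remedy for extreme class imbalance; the
  liver experiment keeps plain BCE.
* **Binarization.** Probability maps are thresholded at 0.5 by default;
  the threshold is an explicit argument everywhere it matters.

## Preprocessing

CT voxel values are Hounsfield units (air ≈ −1000 HU, water = 0 HU).
`window_hu()` clamps to a diagnostic window and rescales linearly to
[0, 1]. The default window [−100, 400] HU is a wide soft-tissue window
under which liver parenchyma sits mid-grey and hypervascular lesions turn
bright; the bounds are fully configurable since the appropriate window is
protocol-dependent. One note on idempotence: re-applying a non-trivial
window to already-normalized data rescales the unit interval again, so
"windowing twice equals windowing once" holds in exactly one consistent
form — windowed data re-windowed with the unit window [0, 1] is unchanged —
and that is the form the tests assert.

Slices are resized to the network grid with bilinear interpolation; masks
use nearest-neighbour so they remain strictly binary. Histogram
equalization (`equalize_image()`) is available as an optional conditioning
step but off by default. Dataset splitting (`split_dataset()`) is a seeded
uniform permutation followed by a prefix/suffix cut with
`round(ratio × n)` training ids — an 8:2 split by default, at the image
level; when patient identifiers are available, splitting the patient list
instead of the slice list avoids cross-patient leakage, and the function is
agnostic about what its ids denote. DICOM series are converted to NIfTI by
a minimal explicit-VR little-endian reader that orders slices by their
ImagePositionPatient z-coordinate, applies the rescale slope/intercept, and
carries spacing and origin into the NIfTI header. Augmentation is
restricted to exact spatial symmetries (flips, quarter-turn rotations)
applied identically to image and masks, so mask binarity and lesion-in-liver
nesting are preserved by construction; `augment()` applies a listed
sequence deterministically and switches to independent coin-flip
application when given a seed.

## The phantom generator

Real hepatic CT with expert annotation cannot be redistributed with a
package, so the test bed is a synthetic phantom: a single-channel
HU-valued slice containing an air background (≈ −1000 HU), a soft-tissue
body ellipse (0–60 HU), one connected liver region (40–70 HU) and 0–5
brighter disc lesions (80–140 HU) nested strictly inside the liver. The
liver boundary is a low-frequency radial deformation of an ellipse
(cosine modes 2–4, amplitudes up to 6%), so boundaries are smooth and
star-convex but not analytic ellipses. Lesion centres are sampled where
the interior distance to the liver boundary exceeds the lesion radius, so
lesions may approach but never cross the boundary, and mutual separation
is enforced so the lesion mask has exactly as many connected components as
placed lesions. Each tissue class receives one constant HU value drawn
from its configured interval; additive Gaussian noise (default 5 HU, a
mild CT-like noise level) is applied last. Generation is bit-reproducible
from `(config, seed)`.

What the phantom does *not* emulate: CT physics (beam hardening, ring and
streak artifacts, partial-volume effects), anatomical texture, multi-organ
context, irregular or infiltrative lesion margins, and 3-D continuity
across slices. Passing the desk-scale experiments therefore shows that the
architecture, gradients, optimizer and metrics work as specified on
high-contrast nested structures — it does not certify clinical-grade
accuracy on real CT, which requires the full-scale corpus and training
budget.

## Training pipeline

`train()` wires the stages together: split, preprocess, seeded weight
initialization (He-normal), Adam optimization, per-epoch training and
validation loss/pixel-accuracy bookkeeping, and best-validation-loss
checkpointing (the returned model carries the best weights; "best" is the
lowest validation loss since no other model-selection rule is implied by
the protocol). Everything stochastic — the split, the initialization, the
batch order, augmentation — derives from the configuration seed, so
identical configurations reproduce identical histories, an invariant the
tests assert literally.

The reference protocol (`train_config()` defaults) is 100 epochs, batch 8,
Adam at 10⁻⁶, 8:2 split. The package's desk-scale experiments use
`train_config_demo()`: 15 epochs, batch 8, Adam at 10⁻³ — at 10⁻⁶ a small
model shows no visible learning within minutes, so the raised learning
rate is the one deliberate deviation in the demo configuration. The
desk-scale problem sizes (80 phantoms of 128 px, 64 of them for training;
a depth-3, base-8 network at 64 px, ~0.4 M parameters) were chosen as the
smallest configuration that still exercises every architectural component
at three resolution levels.

`predict()` replays the preprocessing recorded in the model bundle, runs
the network in inference mode, thresholds, and resizes the mask back to
the input grid (nearest-neighbour). `evaluate_run()` scores the recorded
held-out split at network resolution (ground truth resized to the network
grid, so average Hausdorff distances are in network-grid pixels) and
refuses ids seen during training unless explicitly overridden.

## Evaluation protocol

From the pixelwise confusion counts (TP, TN, FP, FN):

* accuracy `(TP+TN)/(TP+TN+FP+FN)` — flattered by the dominant background,
  and therefore always at least as large as IoU on the same counts;
* Dice `2TP/(2TP+FP+FN)` and IoU `TP/(TP+FP+FN)`, linked by
  `IoU = DSC/(2−DSC)`;
* average Hausdorff distance: the symmetric mean of the two directed mean
  nearest-neighbour distances between boundary point sets (mask minus its
  one-pixel 4-connectivity erosion), Euclidean, in pixels — or millimetres
  when a spacing is supplied. Boundary points rather than full masks are
  used because the metric is meant to measure boundary error; full-mask
  point sets are available via `points = "mask"`. The implementation uses
  an exact Euclidean distance transform; the tests pin it to an all-pairs
  brute-force oracle at 10⁻⁹.
* ROC AUC through the rank-statistic formulation (ties counted half),
  hence invariant under strictly monotone transforms of the probability
  map.

Degenerate inputs are defined rather than left to chance: two empty masks
give Dice = IoU = 1 with a warning; average Hausdorff is undefined for an
empty mask (an error from the metric, recorded as missing by
`evaluate_case()` and excluded, with a count, from aggregates); AUC is
undefined for single-class ground truth and handled the same way.
Aggregation over a case set is the unweighted mean of per-image metrics
(per-image-then-mean, not pixel-pooled).

## Numerical choices

* Convolutions are im2col + GEMM with the patch gather/scatter in C++;
  all backward passes are hand-derived and verified against central finite
  differences at 10⁻⁴ relative tolerance (they agree to ~10⁻⁹).
* Max-pooling breaks ties by first window position; the ×2 up/down
  resampling pairs are exact inverses on the shape level, which is why
  `input_size` must be divisible by `2^depth`.
* Batch normalization uses biased batch variance, momentum 0.1 running
  statistics, epsilon 10⁻⁵.
* BCE probabilities are clamped to [10⁻⁷, 1−10⁻⁷] for the loss value; the
  gradient flows through the logits and needs no clamping.
* Soft Dice uses smoothing constant 1; on hard targets with saturated
  outputs `1 − loss` approaches the hard Dice of the thresholded
  prediction, a relation the tests check.

## Limitations

* 2-D only: slices are segmented independently; no 3-D convolutions or
  volumetric surface-distance metrics.
* Liver and lesion are separate single-task models by default, mirroring
  how the results are reported; a shared multi-task head is out of scope.
* The CPU implementation is meant for desk-scale experiments and testing;
  full-scale training (tens of thousands of 224 px slices, 100 epochs)
  requires a GPU framework and is outside what this package attempts.
* The DICOM reader intentionally supports only uncompressed explicit-VR
  little-endian single-frame series — the common export format — and
  rejects everything else loudly.
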