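---
title: "Multi-task pretraining with gradient accumulation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task pretraining with gradient accumulation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(medmtl)
```

## The problem

Biomedical imaging labels come in incompatible shapes: a whole-slide patch
may carry a single diagnosis, a CT slice a pixel-wise organ mask, a
microscopy field a set of nucleus bounding boxes, and a tomographic volume
one label for a whole stack of slices. Training one representation on all of
them at once runs into two obstacles: the memory cost of traditional
multi-task training grows with the number of tasks (all activations live at
once), and loss functions of different label types have different magnitudes,
so one task can silently dominate the shared encoder.

`medmtl` implements a training strategy that addresses both. Tasks are
assembled as independent computational graphs over one set of *shared
blocks*; a gradient-accumulation (GA) loop runs one task at a time,
accumulating gradients into a single buffer per shared parameter and
updating once per round; and every label type's objective is normalized so
that its value at freshly initialized heads on random inputs is close to 1.

## Shared blocks and task graphs

Three shared blocks serve all tasks:

* an **encoder** mapping an image (values in [0,1], padded bottom/right to a
  stride-32 multiple) to a feature pyramid at strides 4/8/16/32;
* a **pixel-dense decoder** (U-Net-style, skip connections by channel
  concatenation) producing a per-pixel embedding at input resolution;
* a **multi-scale decoder** (feature-pyramid style) producing five maps at
  strides 8/16/32/64/128 for anchor-free detection; two extra levels are
  derived from the deepest pyramid level by stride-2 convolutions so that
  the count is five for any 4-level encoder.

Task heads are deliberately minimal — a single linear layer on the pooled
image embedding for classification-like tasks, a single 1x1 convolution for
dense tasks, and one classification plus one regression convolution for
detection (the centerness convolution lives in the shared multi-scale
decoder). The image embedding is the global average pool of the deepest
pyramid level, which makes its length independent of the input size; a
parameter-free layer norm standardizes it per sample before any linear head,
the usual arrangement in transformer-style classifiers.

The default encoder is a small 4-stage CNN (stage widths 16/32/48/64,
embedding dimension 64) in **pre-norm residual** form: normalization
conditions each convolution's input while the residual stream carries
unnormalized activations. We found the alternative — parameter-free
normalization applied after every convolution — pins every layer's output
distribution regardless of the weights and reliably stalls optimization;
pre-norm placement with identity skips is what makes the parameter-free
setting trainable. Any encoder can be plugged in through
`config$custom_encoder` provided it emits four maps at the contracted
strides.

## Normalization

All normalization in the shared blocks is layer normalization computed per
sample — never over the batch, since batches from different tasks follow
different distributions. Statistics are taken over all channels and spatial
positions of a sample (`scope = "global"`, the default; a per-position
`"channel"` scope is available). Two modes exist:

* `parameter_free` (default): `y = (x - mu) / sigma`, `sigma =
  sqrt(Var(x) + eps)`, `eps = 1e-5`; contributes zero trainable parameters.
* `affine`: adds per-channel gain `gamma` (init 1) and bias `beta` (init 0).

`replace_normalization()` walks any module tree and swaps every
normalization layer for the configured variant; it is idempotent, and the
blocks are built with conventional batch-normalization placeholders that are
replaced at construction, mirroring how one would adapt an off-the-shelf
CNN.

## Loss normalization

* **Multiclass**: categorical cross-entropy in nats divided by `log(C)`.
  At uniform predictions the expected value is exactly 1 for any number of
  classes. (The multiplicative variant is available as `eq1_literal = TRUE`;
  it makes the random-init loss `log(C)^2`, which contradicts the
  design goal of comparable magnitudes, so division is the default.)
* **Multilabel**: mean element-wise binary cross-entropy times
  `log2(e) = 1.44269` — a nats-to-bits conversion putting chance-level loss
  at exactly 1.
* **Segmentation**: `0.5 * Dice + 0.5 * Focal` on softmax probabilities.
  Dice smoothing is 1 in numerator and denominator; the focal exponent is
  `gamma = 2` (no alpha weighting in the multiclass focal term).
* **Detection**: `L_cls / C + L_reg + L_ctr`, with a binary focal
  classification loss (`gamma = 2`, `alpha = 0.25`) over all pixels of all
  levels, an IoU loss on foreground pixels, and binary cross-entropy on
  centerness, each normalized by the foreground-pixel count.
* **Slice MIL**: volumes are cut into slices; slice embeddings are combined
  by a learned weighted average (a linear score per slice followed by a
  softmax, so weights are nonnegative and sum to 1 and the bag embedding
  stays in the convex hull of the slice embeddings), then classified by the
  same linear-head machinery as 2D images.

## The training loop

`train()` follows the GA scheme: the infinite task sampler yields one batch
of each task per optimization round (tasks restart their shuffled data
stream transparently on exhaustion, so no dataset lengths are needed);
each task's loss is backpropagated immediately and its activations released;
at an update step one AdamW step is applied to the summed gradients and the
buffers are cleared. Because summation is commutative, task order within a
round cannot affect the update — the test suite verifies the accumulated
gradient against central finite differences of the joint summed loss (the
independent oracle) and under task-order permutations.

Optimizer settings follow the transformer-pretraining convention: AdamW
with learning rate 0.001 and weight decay 0.05 for pretraining. Downstream,
two groups are used: shared blocks at 1e-5 and the task head at 1e-4, for a
fixed 100 epochs in both the frozen and fine-tuning settings, with no
validation set. The frozen *linear probe* trains only a convex head, so a
larger default rate (0.01) is appropriate there; it was chosen a priori from
the convexity argument, not tuned. Per-task RNG streams are derived from the
master seed, so adding a task never perturbs another task's data order.

## Intensity handling and caching

Inputs are normalized to [0,1]: 8-bit images by division by 255; CT volumes
min-max; MRI volumes by clipping to the (2.5%, 97.5%) intensity quantiles
(robust to scanner-dependent outliers). Constant-valued inputs map to 0.5
rather than erroring, which keeps degenerate synthetic cases running.
Volumes are sliced along the last axis after normalization; orientation
augmentation of a volume is permitted only when `max(shape) <
2 * min(shape)` (roughly isotropic). The patch cache stores raw patches
under LRU eviction and applies patch-level augmentation on every retrieval,
so load-time (3D) augmentation happens once per load and 2D augmentation on
every fetch, without mutating the cached raw patch.

## The synthetic shapes suite

All desk-scale data come from a deterministic generator of geometric-shape
scenes (circle, square, triangle, cross, and a held-out ring class for
out-of-domain experiments). A scene places non-overlapping shapes by
rejection sampling; each shape is rendered as a mildly textured interior
(zero-mean oriented stripes, so the interior mean matches the background)
with a bright 2-px contour band. Scene mean intensity therefore tracks shape
*area*, never shape *type*, and the suite's non-triviality guard verifies
that a classifier on mean intensity alone stays well below the transfer
benchmark's bar. An earlier all-noise texture design (interiors
distinguished from background only by noise variance) turned out to be
effectively unlearnable even for a hand-crafted local-variance oracle and
was replaced by the contour rendering — chosen once, on the grounds that a
fixture must be solvable by the model class it exercises.

The default suite has one task per label type with deliberately
heterogeneous geometry — image sizes 32–96 px, 1 and 3 channels, dataset
lengths 40–160 — to exercise variable-size handling and the sampler's
restart logic. These sizes are desk-scale choices: the real systems this
framework models train on 224–512 px patches from public medical datasets,
and nothing in the code restricts patch sizes beyond the [32, 1024] contract.
What passing the suite shows is that the mechanics (graph assembly, GA
equivalence, loss normalization, transfer of frozen features) behave as
specified; it does not show that any particular medical signal is learnable.

Training datasets carry an augmentation policy applied by the training loop:
flips, transposition and ±6 px translations for image-level labels
(shape classes are invariant to these), photometric jitter everywhere.
Without augmentation the small suite is memorized and frozen-probe transfer
degrades noticeably.

## The transfer benchmark

`pretrain_transfer_benchmark()` is the package's end-to-end demonstration:
20 epochs of GA pretraining on four suite tasks (two classification tasks,
multilabel, segmentation; 160 optimization-loop steps per epoch, i.e. two
passes over the largest dataset), then frozen linear probing on a held-out
shape-classification task with 50 labels against a random-initialization
frozen baseline. The probed encoder must reach macro-F1 at least 0.90 and
beat the random baseline by at least 0.10. Problem sizes were fixed at the
values above so a full run completes in minutes on one CPU core.

## Numerical choices and edge cases

* Boxes are half-open `[x0, x1) x [y0, y1)` in 0-based pixel coordinates; a
  stride-`s` map cell `(i, j)` sits at image location `((j+0.5)s,
  (i+0.5)s)`. Regression logits encode `exp(x) * stride` distances.
* Detection level assignment routes a box to the level whose range
  (0–64, 64–128, 128–256, 256–512, 512–Inf px) contains its largest edge
  distance; pixel ties go to the smaller-area box. Decoding multiplies class
  score by centerness and suppresses at IoU 0.5 per class (greedy NMS),
  score threshold 0.05.
* Degenerate cases: constant inputs normalize to 0.5; all-zero centerness
  distances return 0; a zero-variance paired difference is reported as a
  degenerate t-test rather than a number; fractions that would select an
  empty class are raised to one sample with a warning.
* mAP is computed at IoU 0.5 with 101-point interpolation; "average F1" is
  macro (unweighted over classes). Both conventions are config-visible
  choices since the field uses several.

## Known limitations

* The default encoder is intentionally small; nothing desk-scale is claimed
  about Swin-class encoders beyond contract compatibility.
* The MIL probe uses uniform slice averaging in the frozen setting (the
  attention scorer is part of the trainable head, so the frozen convex probe
  cannot adapt it).
* Whole-slide pyramids are abstracted behind loader callables; no actual WSI
  decoding is included.
* Single-process training only; the memory argument for GA (activations of
  one task at a time) holds, but no distributed execution is provided.
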