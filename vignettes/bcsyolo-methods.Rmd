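---
title: "Lightweight star-attention detection for body condition scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight star-attention detection for body condition scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Body condition scoring (BCS) rates a dairy cow's subcutaneous fat reserves on
an ordinal 1–5 scale in 0.25 steps; in intensive dairying only the central
band (3.25–4.25) is common. Automated scoring from overhead 2D cameras frames
this as single-class-per-image object detection: find the tail-head region in
the frame and assign it one of five ordinal classes. For on-farm deployment
the detector must be small, and the constraint drives the architecture: every
design choice in this package trades accuracy-relevant capacity against
parameters and FLOPs.

`bcsyolo` implements the full architecture family as a self-contained R
library: the baseline single-stage detector, its progressively lightened
variants, channel-wise knowledge distillation between a large teacher and the
compact student, deterministic profiling of each variant, and a synthetic data
generator that stands in for the (external) farm dataset so the whole training
and evaluation path can be exercised offline.

## Architecture

All variants share the same skeleton, a YOLOv8-lineage graph: a strided stem,
four feature stages (each a "C2f" block: channel split, `n` stacked inner
bottlenecks with partial concatenation, 1×1 fuse convolution), an SPPF
pooling block, a PAN neck with four more C2f fusion blocks, and a three-level
detection head at strides 8/16/32. Top-level modules carry a stable 0–22
numbering; the four neck fusion outputs sit at indices 12, 15, 18, 21 and are
the distillation sites. The n-scale uses width multiplier 0.25 (16–256
channels), the s-scale teacher 0.5.

### Star blocks

The *star operation* multiplies two linearly transformed copies of a feature
element-wise. For maps `w1`, `w2` on a bias-augmented input `x` of length
`d + 1`,

$$(w_1^\top x)(w_2^\top x) = \sum_{i}\sum_{j} w_1^i w_2^j x_i x_j,$$

so one cheap multiplication implicitly spans all $(d+1)(d+2)/2$ pairwise
monomials — a high-dimensional nonlinear feature space at linear cost.
(The count is exposed as `implicit_monomial_count()`; tests verify the
expansion identity against a brute-force double sum.)

The star block realizes this as: depthwise conv → two parallel 1×1
expansions (ratio 3) → SiLU on branch one → element-wise product → 1×1
projection → second depthwise conv → residual. `c2f_star*` variants replace
every C2f inner bottleneck (two 3×3 convolutions, $36c^2HW$ FLOPs) with this
block ($\approx 18c^2HW$ at ratio 3), which is where the 8.2 → 7.0 GFLOP drop
comes from.

Two internals are not fixed by the architecture description and were
calibrated once against the published per-variant budgets (parameters, FLOPs,
checkpoint MiB) of the ablation: the pointwise expansion ratio (3, which is
also the cited StarNet default) and the depthwise kernel (5). Ratio 2 matches
the FLOP row but undershoots the size rows by ~6%; ratio 3 with kernel 7
overshoots the FLOP row by ~3%. Ratio 3 with kernel 5 reproduces all rows
within ~1%. These are architecture constants, not tuning knobs, and are fixed
in the defaults.

### EMA attention

Efficient multi-scale attention splits channels into `G` groups and, per
group, pools globally along the width (height descriptor $z^H(c,i)$) and
along the height (width descriptor $z^W(c,j)$), concatenates the two
descriptors along the spatial axis — H first, then W; the order is part of
the contract — applies a shared 1×1 convolution and a sigmoid, splits back
into per-direction gates, and modulates the input multiplicatively:

$$z = \sigma\!\left(W_1\,[z^H \oplus z^W]\right).$$

`ema_variant = "paper_eqs"` implements exactly this gate and is the normative
path for `ema_forward()`. The assembled models default to
`ema_variant = "full_cited"`, the complete module from the attention
literature, which adds a per-group 3×3 branch and a cross-spatial interaction
(softmaxed global descriptors of each branch attending over the other's
spatial map). The budget evidence forces this choice: the gate alone costs
~0.05 GFLOPs across the eight replaced blocks, which cannot account for the
published 7.0 → 8.1 GFLOP step of the "+EMA" ablation row, while the full
module at `G = 4` reproduces it within 1%. `G = 4` (rather than the more
common 8 or 32) is likewise fixed by that calibration; with `G = 8` the row
undershoots by ~4%. EMA is applied once per composite block, after the C2f
fuse convolution — per-inner-block placement would overshoot the budget.

### SSLDH head

The baseline decoupled head spends ~35% of the model's FLOPs: per level, two
private 3×3 conv stacks for regression and classification. The shared
lightweight head (SSLDH) replaces it with: per-level GroupNorm 1×1 adapters
to a shared width, one shared GroupNorm 3×3 convolution, a star-style FC
interaction (two parallel 1×1 maps, SiLU on one branch, element-wise
product), a second shared GroupNorm 3×3 convolution, shared 1×1 regression
(`4 * reg_max` channels) and classification (`num_classes` channels) output
convolutions, and one learnable scalar per level on the regression branch
(compensating stride-dependent regression ranges, as in shared-head
detectors of the FCOS lineage). GroupNorm (per-sample, per-group moments)
makes the head batch-size independent, which matters for single-image
inference.

Free constants calibrated against the published budgets: shared width 56
(GroupNorm groups 14, the largest divisor ≤ 16) and expansion 1.5 of the FC
interaction (hidden 56 → 84 before the product, matching the "project high,
compute low" description of the head). Output convolutions are shared across
levels (`reg_max = 16` bins, as in the baseline lineage); per-level output
convolutions remain available as a config flag.

### Box decoding

Regression logits per cell form four distributions over `reg_max = 16` bins;
the expected bin index (softmax expectation) gives the distance to each box
side in stride units around the cell-center anchor. Classification logits
pass through a sigmoid. Decoding is anchor-free; boxes are clipped to the
image.

## Training

Defaults mirror the study conditions: 100 epochs, batch 16, SGD (momentum
0.937, weight decay 5e-4 on kernels), initial learning rate 0.01 decayed
linearly, input 640, HSV jitter 0.015/0.7/0.4, translate ±0.1, scale gain
0.5, horizontal *and* vertical flips at 0.5 (sensible here because the
camera looks straight down), NMS IoU 0.7. The loss is the baseline lineage's
composite: CIoU on decoded boxes (gain 7.5), BCE on class logits (0.5),
distribution-focal loss on the bin distributions (1.5). Positive anchors are
assigned statically: cells whose centers fall inside the ground-truth box,
top-10 by center distance across the three levels (nearest anchor as a
fallback for degenerate boxes). This is simpler than task-aligned
assignment, but the architecture work does not touch the assigner and the
static rule is deterministic and sufficient at the problem sizes used here.
Gradients are clipped to a global norm of 10.

Numerical notes: the network engine is exact reverse-mode differentiation
composed from primitives (im2col + BLAS GEMM convolutions in C++, batch/group
norm, SiLU, max-pool, nearest upsampling); every primitive and every
composite block is verified against central finite differences in the test
suite. The one deliberate exception is the CIoU term, whose gradient with
respect to the four decoded distances is itself computed by central
differences per positive anchor (an O(1) cost; the penalty terms are
piecewise smooth) and then chained analytically through the softmax
expectation.

## Channel-wise distillation

Each channel's activation map is softmax-normalized over its spatial
positions at temperature `T` (default 4, the convention of the cited
channel-distillation work; the architecture paper leaves it unstated); the
distillation loss is

$$\frac{T^2}{C}\sum_c \mathrm{KL}\!\left(\phi_T(t_c)\,\|\,\phi_T(s_c)\right),$$

summed over the four registered layer pairs (12/15/18/21 on both sides) with
a constant weight (default 1). Teacher activations are constants; gradients
reach only the student and the 1×1 adapters that reconcile teacher/student
widths (identity-initialized when widths agree, droppable after training so
the deployed student graph is unchanged). Feature-map distillation is the
exercised mode; logits-mode is accepted in the config but untested against
any published number.

`calibrate_bn()` exists because inference-mode BatchNorm needs running
statistics: distillation compares the teacher's inference-mode features with
the student's training-mode features, so a teacher whose statistics are
uncalibrated (or a student copy thereof) would see a spurious mismatch. The
calibration pass overwrites the running moments with one batch's (biased)
statistics, after which a student that copies the teacher's weights has
exactly zero distillation loss — a property the tests assert.

## Profiling conventions

* **FLOPs** = 2 × multiply-accumulates of convolutions, linear maps and the
  attention module's matrix products, at a stated input size, per image.
  Normalization, activation, pooling and elementwise terms count zero
  (treated as fused). This is the convention under which the published
  budgets reproduce; it is implemented twice — an analytic graph walker and
  a runtime hook counter — which the tests require to agree within 1%.
* **Size** = bytes of the saved checkpoint with all tensors (weights and
  normalization buffers) stored as IEEE half precision, reported in MiB
  (2^20 bytes). The container adds a JSON header of well under 2% of the
  payload. Published sizes that include a heavyweight serialization format's
  overhead (~0.15 MiB) will read slightly above ours; the effect is ~3% on
  the baseline row and <1.5% on the compact variants.
* Parameter counts include learnable tensors only.

At n-scale with 5 classes and 640×640 input the four variants profile at
8.09 / 7.06 / 8.02 / 6.54 GFLOPs and 5.78 / 4.95 / 5.18 / 3.95 MiB
(baseline / star / star-EMA / full), with the s-scale teacher at 28.4 GFLOPs
and 21.3 MiB; `scripts/acceptance.R` recomputes these from scratch.

## Synthetic data

The generator emulates the acquisition regime of the real task: overhead
alleyway frames at a native 1297 × 720 render, one labeled tail-region object
per image, five ordinal classes. Classes differ through a single monotone
latent — ellipse elongation plus the depth of a ring-shaped contour groove —
so misclassifications concentrate on adjacent classes, mirroring the ordinal
structure that makes near-boundary body condition scores hard. Brightness
jitter and background clutter are always on; directional motion blur
(normalized line kernel, default horizontal — the direction of travel along
the alleyway) is an evaluation-time perturbation with replicate-padded
edges, so constant regions are preserved and the blur is mean-preserving.
The per-class split is floor(0.8·n) to train, remainder to validation
(documented because real published counts are rarely an exact 80/20).

What the generator does **not** emulate: real coat texture and color
variation, multiple animals per frame, occlusion, perspective distortion,
and real label noise. Passing tests therefore demonstrate that the training,
evaluation and distillation machinery is correct and that the architecture
separates an ordinal shape latent under nuisance variation — not that the
reported real-data accuracy transfers.

Default `n_per_class = 40` (200 images) matches the desk-scale regime the
smoke tests run at. The blurred-set evaluation replaces the sampled images
with their blurred versions (the published protocol does not state replace
vs. augment; replacement is implemented and flagged here).

## Problem sizes used by the test suite

Deterministic profiling runs at the full 640×640 — those numbers are
size-exact. The learning smoke tests run scaled down, chosen once as the
smallest sizes at which every direction-of-effect is still measurable: 200
images rendered at 324×180, network input 96, 10 training epochs (the loss
decrease is asserted at epoch 5, evaluation after epoch 10, where the
synthetic validation mAP@50 clears the 1/num_classes chance proxy),
distillation for 50 full-batch steps from a perturbed copy of the trained
model at learning rate 1e-4 without momentum and with a
distillation-dominant weight (30): the loss magnitude is a free constant of
the method, and at weight 1 the detection gradient — orthogonal to the CWD
gradient and several times larger — gives the CWD component a random walk
rather than a visible descent. Near the distillation optimum and with the
CWD term dominant the decrease is strictly monotone. Blur robustness is
compared between kernels 3 and 35 on the full validation split.

## Known limitations

* Single-process CPU execution; `workers` in the training config is recorded
  for interface compatibility only.
* The assigner is static (center + top-k), not task-aligned; mosaic
  augmentation and EMA-of-weights are not implemented. Both belong to the
  baseline's training bag of tricks, not to the architecture contribution.
* Rotated boxes, keypoints, and multi-teacher distillation are out of scope.
* The alternative attention modules of the comparison study (ELA, LSKA,
  SCConv) are not implemented; the C2f composite exposes the attention slot
  (`ema_variant`) where they would plug in.
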