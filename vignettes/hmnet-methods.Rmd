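---
title: "Methods: a lightweight multi-resolution 3D segmentation network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight multi-resolution 3D segmentation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hmnet)
```

## The problem and the model

Multi-modal MRI brain-tumor segmentation assigns each voxel of a
240×240×155, 1 mm³ volume one of the labels background / necrotic and
non-enhancing core (1) / edema (2) / enhancing tumor (4), given four
co-registered modalities (FLAIR, T1, T1c, T2). Evaluation uses three
nested regions: whole tumor (labels 1∪2∪4), tumor core (1∪4) and
enhancing tumor (4). Note the region nesting ET ⊂ TC ⊂ WT is a property
of the label semantics, and this package exploits it end to end: the
network's three output channels score exactly these regions.

The backbone follows the high-resolution-network idea rather than an
encoder–decoder: a full-detail branch is kept at the stem's half
resolution throughout, and each of the first three stages adds a branch
with half the resolution and twice the channels of the previous lowest
(32@`/2`, 64@`/4`, 128@`/8`, 256@`/16` relative to the input). Stages
apply one lightweight conditional channel weighting (LCC) block per
branch and end with a lightweight multi-resolution fusion (LMRF); the
head upsamples all branches to the finest branch grid, concatenates 480
channels, reduces to 32 with a 3×3×3 conv block, upsamples, adds the
stem's full-resolution map, and classifies pointwise.

## Architectural conventions

Several structural details are under-determined by the published
description of this family of networks; the package fixes them as
follows, choosing in every case the reading consistent with the printed
per-layer tables and the printed totals (0.80 M parameters, 129.4 G
operations at 128³). These choices are load-bearing for the complexity
figures and are asserted by the test suite.

- **Where normalization lives.** Group normalization (8 groups, clamped
  to the channel count) + ReLU follow only the three dense "conv block"
  layers: the two stem convolutions and the 480→32 head convolution. The
  lightweight blocks and fusion paths are norm-free; their weighting
  units already bound activations through sigmoids. With affine terms
  everywhere the parameter total would drift to 0.81 M.
- **Biases.** No convolution carries a bias except the final classifier
  (3 parameters). This is the shuffle-block convention.
- **The classifier is 1×1×1.** A 3×3×3 classifier at full resolution
  would add 5.4 G operations to the 129.4 G budget; the pointwise
  classifier is also the standard high-resolution-network head.
- **CWU input set and weight slice.** The weighting unit of branch *b*
  sees its own post-split half plus the *full* (pre-split) maps of every
  other active branch — at stage 2 that is 16 + 64 = 80 channels, the
  printed width. The own half leads the concatenation, and the weight
  slice returned to the branch is the leading block aligned with it.
- **The 1-D channel convolution acts at the pooled extent.** Because one
  shared kernel slides along the channel axis identically at every voxel,
  it commutes exactly with global average pooling; the implementation
  applies it on the pooled (coarsest-branch) grid and then reduces, which
  is how the per-layer table accounts it. `cwu_kernel_size(C)` truncates
  `log2(C)/2 + 1/2` to an integer and promotes even values to the next
  odd — 3 kernels for 8–63 channels, 5 for 64–1023 — and is monotone.
- **SWU width.** The two pointwise convolutions keep the channel count
  (C→C→C); no bottleneck ratio.
- **Depthwise separable means.** Channel-preserving 3×3×3 convolutions
  inside LCC blocks are purely depthwise; whenever the channel count
  changes (fusion downsampling, ghost reduction) a pointwise convolution
  provides the mixing. Fusion downsample chains double channels at every
  stride-2 hop.
- **Fusion is linear.** Lateral contributions are summed with no
  activation, so a fusion layer with zero lateral weights is exactly the
  identity on each branch — a property the tests rely on.
- **Channel shuffle uses two groups**, matching the two concatenated
  halves; shuffling with `g` and then `C/g` restores the original order.

## Counting parameters and operations

`conv_params()` and `conv_flops()` evaluate the closed forms
`k³·(Cin/groups)·Cout` and `ops_per_mac · k³·(Cin/groups)·Cout·d·h·w`.
`conv_flops()` defaults to `ops_per_mac = 2` (a multiply and an add per
multiply-accumulate), and for any dense bias-free layer the identity
`flops = 2 · params · d·h·w` holds exactly.

`model_complexity()` walks the layer registry that the model builder
emits — every convolution with its kernel, channels, groups and output
extent, every normalization with its affine parameters — so the report is
exact for the model as constructed, not for an idealised plan. Its
*totals* default to `ops_per_mac = 1`: the comparison tables that this
family of networks is benchmarked in report fused multiply-accumulate
counts (a 3D U-net at ~1670 G, lightweight networks at tens of G), and
the package reports on the same scale; pass `ops_per_mac = 2` for the
two-operations-per-MAC convention. Normalization, activation, pooling and
upsampling contribute no counted operations. "M" and "G" are decimal
(10⁶, 10⁹), printed to two and one decimals respectively.

## Metrics

`dice_coefficient()` is 2TP/(FP+2TP+FN), with 1 for two empty masks.
`hd95()` extracts boundary voxels under 6-connectivity (volume borders
count as outside), computes both directed distance sets exhaustively in
mm, and combines the two directed 95th percentiles (type-7 quantiles)
with a max; `percentile = 100` gives the classic Hausdorff supremum form,
also exposed as `hausdorff_distance()`. An empty mask on either side
returns the benchmark penalty constant 373.13 mm. ET is label 4; the
alternative reading (label 1) contradicts both the nesting semantics and
the benchmark's convention. The test suite proves the implementation
equal to an independent exhaustive pairwise oracle on a thousand random
masks up to 8³.

## Preprocessing and augmentation

Each modality is z-scored over its nonzero (brain) voxels with the
population standard deviation, leaving background at exactly 0; a
constant brain region maps to 0 and an all-zero modality warns.
Augmentation mirrors each axis independently with probability 0.5 and
rotates in the axial plane by an angle uniform in (−10°, 10°) — linear
interpolation for images, nearest-neighbour for labels so the label set
is preserved. Volumes pad to multiples of 16 (the BraTS slice axis
155 → 160) before cropping; training crops are positioned to contain a
uniformly drawn tumor voxel when a label exists, inference uses the
centered window with the offsets recorded for exact paste-back.

## Training

The loss is the mean over the three region channels of soft Dice loss
plus binary cross-entropy on sigmoid scores — region heads make the
nesting trivially consistent after thresholding (ET ⊆ TC ⊆ WT is enforced
hierarchically in `predict_labels()`). Optimisation is Adam at an initial
learning rate of 1e-4 with batch size 2 and up to 500 epochs, the
benchmark protocol, with no schedule (only the initial rate is part of
the protocol); `max_steps`, `patience` and `stop_dice_wt` bound
desk-scale runs. Five-fold splits shuffle once with a fixed seed and give
the remainder cases to the earliest folds (11 cases → 3,2,2,2,2).
Parameters use He initialisation (gain 2 over fan-in); normalization
starts at identity. Gradients flow through hand-written backward passes
(im2col + BLAS GEMM for dense convolutions, direct kernels for depthwise,
closed-form group-norm and loss gradients) and are verified against
central differences down to ~1e-9 relative error; cross-entropy
probabilities are clamped at 1e-7 for finiteness.

## The synthetic phantoms

`make_phantom()` builds an ellipsoidal brain containing three nested
tumor ellipsoids (edema shell = label 2, core shell = label 1, enhancing
center = label 4) with mildly jittered radii — default 14/9/5 voxels at a
64³ extent, scaled with the extent — and renders four channels from a
modality × tissue contrast table (edema brightest on FLAIR/T2, enhancing
core brightest on T1c) plus Gaussian noise (sd 0.05) inside the brain;
the background is exactly zero and every case is reproducible from
`(seed, case_seed)`. The phantoms emulate the benchmark's layout,
geometry, nesting and coarse modality contrast; they deliberately lack
texture, bias fields, multifocality and anatomical variability. Tests
passing on phantoms therefore establish that the pipeline is correct and
that the network can fit a segmentation target — not that it reaches any
particular accuracy on real MRI, which requires the registered dataset
and GPU-scale training and is out of scope here.

## Problem sizes used in the checks

The shipped checks run on one CPU: structural and gradient tests use a
width-8 network at 16³; the forward shape-plan check runs the full-width
network at 32³ (the 128³ plan is verified analytically from the layer
registry, as a full 128³ pass needs ~260 GFLOP and multi-GB activations);
the learnability check overfits one 64³ phantom with 32³ tumor-biased
crops at learning rate 1e-3 (a 300-step overfit run, distinct from the
1e-4 full protocol default), evaluating whole-volume Dice every 25 steps
and stopping above 0.95 — it passes 0.9 within the first few dozen steps.
Complexity accounting always runs at the full default configuration.

## Known limitations

Batches are accumulated case-by-case rather than vectorised; training at
the full 128³ protocol scale is impractical on CPU (the package targets
method study and verification, not benchmark submission). Sliding-window
inference averages raw scores over overlapping windows, which slightly
smooths boundaries. The exhaustive surface-distance computation is
quadratic in surface size — fine up to ~64³ phantoms, slow for full
240³ volumes with large lesions.
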