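---
title: "Methods: the SPA-UNet segmentation model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SPA-UNet segmentation model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`spaunet` implements SPA-UNet, an encoder–decoder convolutional network for
semantic segmentation of liver and liver-tumor regions in 2-D abdominal CT
slices (labels 0 = background, 1 = liver, 2 = tumor). Liver tumors in CT are
low-contrast, fuzzy-boundaried, and variable in shape, size and count; the
architecture addresses this with multi-scale dilated convolutions in the
encoder and attention-gated residual blocks in the decoder.

The encoder alternates five **spatial pyramid convolution blocks (SPCB)**
with four **spatial pyramid pooling blocks (SPPB)**; the decoder alternates
four bilinear **Upsample** steps (each concatenated with the matching
encoder skip) with four **residual attention blocks (RA-Block)**, and a 1×1
convolution head emits per-pixel class scores. With the default channel
ladder the SPCB outputs carry 64/128/256/512/1024 channels, the SPPB outputs
128/256/512/1024, the concatenated Upsample outputs 1536/768/384/192 and the
RA-Block outputs 512/256/128/64; `audit_shapes()` verifies this ladder
mechanically on a live forward pass.

**SPCB.** Three parallel 3×3 dilated convolutions (rates 1, 2, 4 by
default), each mapping `in_channels -> out_channels`, are summed
elementwise; the sum is gated by parameter-free channel attention (GCT-B0),
batch-normalized, and PReLU-activated. Each branch owns independent kernel
weights: the elementwise sum requires equal branch output widths, and
independent weights are the standard, strictly more expressive reading.
PReLU slopes are learnable per channel and initialized at 0.25, so at
initialization the activation is exactly `x` for `x >= 0` and `0.25x`
otherwise.

A note on receptive fields: a single 3×3 convolution with dilation `r` has a
one-axis receptive field of `3 + 2(r-1)` pixels — 3, 5 and **9** for rates
1, 2 and 4. Descriptions of this architecture sometimes quote "3, 5, 7" for
the three branches; 7 is not consistent with the span formula (or with
impulse tracing, which the test suite performs), so `receptive_field_3x3()`
returns the formula value and this discrepancy is documented rather than
reproduced.

**GCT-B0.** The channel attention is the parameter-free Gaussian-excitation
gate: channels are globally average-pooled, the pooled vector is
standardized across channels (epsilon 1e-5 guards degenerate inputs such as
1×1 spatial maps), and each channel is scaled by `exp(-z^2 / (2 c^2))` with
fixed `c = 2`. Gates lie in (0, 1]; disabling the attention removes exactly
the gating step and nothing else, and changes the parameter count by zero.

**SPPB.** Downsampling halves the spatial size through two branches. When
`C_in < C_out`, 2×2 non-overlapping max pooling carries the original `C_in`
channels and a 3×3 stride-2 convolution (padding 1, then BN + PReLU)
produces the remaining `C_out - C_in`; the branches are concatenated, pool
half first. When `C_in >= C_out` the pooling branch is dropped and the
convolution alone produces all `C_out` channels.

**Upsample.** Bilinear interpolation doubles the spatial size under the
half-pixel-center convention (no corner alignment); the result is
concatenated with the corresponding encoder SPCB output. Skips are taken
from SPCB outputs pre-downsampling — the only wiring consistent with the
concatenated widths (1024 + 512 = 1536, and so on). The convention is fixed
because interpolation values are asserted against hand-computed weights in
the tests.

**RA-Block.** The main branch applies two 3×3 convolutions (each BN, PReLU
between them); the shortcut applies a 1×1 convolution, BN, then coordinate
attention. The branch outputs are summed on post-BN, pre-activation maps and
a single PReLU follows the sum — standard pre-activation residual practice,
and the convention that makes the additive fusion exactly an elementwise sum
of the two branch maps (which the tests assert at the fusion node).

**Coordinate attention.** Features are average-pooled along each spatial
axis, the two descriptors pass through a shared 1×1 bottleneck (reduction
32 with a floor of 8 intermediate channels — the floor avoids zero-width
bottlenecks at the 64-channel decoder level), a ReLU, and two sigmoid gate
heads producing a row gate (C×H) and a column gate (C×W) multiplied back
into the map. Plain sigmoids are used for the gates; gates therefore lie
strictly in (0, 1).

Convolution weights are He (fan-in) normal; BN is initialized at gamma 1 /
beta 0 with running statistics updated as `0.9 * old + 0.1 * new` and used
in eval mode. Convolutions feeding a BN omit their bias.

## Preprocessing and data handling

CT intensities are windowed with width 200 HU, level 60 HU — the retained
interval [-40, 160] HU is rescaled linearly onto [0, 1] so the network input
range is fixed. Slices whose masks contain no nonzero label are removed; a
hypothetical tumor-without-liver slice is *retained* (inclusive rule: in
LiTS-style data tumors lie inside the liver so the readings coincide; on
synthetic data the inclusive rule is the safer one).

The random split assigns `ceiling(fraction * N)` slices to validation and to
test and the remainder to training. This convention reproduces the published
slice counts exactly (19,211 slices at 0.8/0.1/0.1 gives 15,367 / 1,922 /
1,922) where plain rounding would not (`round(0.1 * 19211) = 1921`). The
split is by slice, matching those counts; a patient-level split is the
methodologically safer alternative for real studies and can be had by
splitting the volume list before slicing.

Augmentation applies, in order: random scaling (0.8–1.2), random horizontal
flip (p = 0.5), random pad-and-crop back to the original size, and random
photometric distortion, defined here as brightness/contrast jitter of at
most ±10% on the image only. Masks travel through the identical geometric
transforms with nearest-neighbor interpolation, so no new labels can appear.
All randomness is a pure function of the per-call seed.

## The phantom generator

`generate_phantom()` renders a noisy background, one smooth elliptical
"liver" (semi-axes 28–42% of the slice side, random orientation and a small
center jitter), and 0–3 circular "tumor" blobs of radius 2–12 px placed
strictly inside the liver (a one-pixel interior margin keeps discretized
blobs off the liver boundary; placement is re-sampled up to 100 times before
erroring). Intensities are background 0.20, liver +0.35, tumors −0.12
relative to liver — tumors are deliberately low-contrast and hypodense — and
the rendered image is blurred with a 1.5-px Gaussian before adding noise
(sd 0.03), emulating fuzzy boundaries. The mask is the exact pre-blur
geometry. Each slice is a pure function of its seed.

What the phantoms do *not* emulate: anatomy other than the liver, intensity
inhomogeneity and scanner artifacts, irregular tumor shapes, 3-D slice
correlation, and the extreme class imbalance of whole-abdomen CT. Passing
the desk-scale learning tests therefore demonstrates that the architecture,
gradients and training loop are correct and can fit structured
low-contrast targets — not that the published LiTS accuracy is reproduced,
which requires the full 131-volume dataset and GPU-scale training.

## Training engine

Defaults equal the published recipe: SGD with momentum 0.9, learning rate
0.01, weight decay 4e-5, batch size 4, 50 epochs, unweighted pixelwise
cross-entropy, constant learning rate (a polynomial-decay schedule, power
0.9, sits behind `schedule = "poly"`). Weight decay applies to convolution
and attention transform weights only — not biases, BN or PReLU parameters —
per common practice. An optional `class_weights` argument exists for the
class-imbalance variant but is off by default, matching the recipe.
Validation runs every epoch when a validation set is supplied; the best
checkpoint is selected by the mean of liver and tumor IoU, a rule chosen
here since none is published. Training aborts with the offending epoch/step
if the loss becomes non-finite. Given a seed, initialization, shuffling and
hence final weights are exactly reproducible.

All forward/backward passes are authored in the package (C++ im2col + GEMM
convolution core; vectorized R for the other layers) and every layer's
backward pass is validated against central finite differences in the test
suite at relative error below 1e-6.

## Metrics

Per class (liver = 1, tumor = 2), one-vs-rest pixel confusion counts feed
IoU = TP/(TP+FN+FP), Precision = TP/(TP+FP), Recall = TP/(TP+FN). The
package defaults to **micro** aggregation (pool counts over all slices,
then compute) — the common LiTS convention, invariant under slice
duplication; **macro** (mean of per-slice metrics over slices containing
the class in either mask) is available behind a flag, and every report
records which was used. When a class is absent from both masks the metrics
return 1.0 by convention and the report flags it — this prevents undefined
0/0 from contaminating tumor scores on tumor-free slices in macro mode.

## Numerical choices and desk-scale sizes

* Max-pool ties route gradient to the first maximum (deterministic).
* BN uses population variance within a batch; epsilon 1e-5 everywhere.
* The empty-denominator metric convention is 1.0, flagged in reports.
* Bilinear resize matrices are dense per-axis operators; their transposes
  are the exact adjoints used in the backward pass.
* Test-suite problem sizes: the channel-ladder audit runs the full default
  ladder (64…1024) on 64×64 inputs; learning and ablation checks run a
  narrowed ladder (16/32/64/128/256 and 4/8/12/16/24) at full architectural
  depth on 64×64 and 32×32 phantoms. These sizes exercise every code path
  (including all four downsamplings) while keeping the default test run
  fast; end-to-end shape conservation is asserted for inputs 64, 96 and 128.
* The overfit check trains on eight 64×64 phantoms guaranteed to contain
  1–3 tumors each, so the tumor-IoU target is well defined on every slice.

## Known limitations

Single-threaded CPU execution bounds practical problem sizes well below the
published 512×512 / 19k-slice scale; no mixed precision, no GPU, no 3-D
context (the model is strictly 2-D, as published); DICOM ingestion and HU
calibration are out of scope (NIfTI volumes are assumed already in HU); and
the published LiTS accuracy tables are not reproduced here for the reasons
above. The "3-channel" network input is produced by replicating the
windowed slice; stacking adjacent slices (2.5-D) is a plausible alternative
reading that the data layer could provide, but replication is the default.
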