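---
title: "Methods: two-stage ensemble segmentation of liver and lesions in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ensemble segmentation of liver and lesions in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
choices that were genuinely open, and what the desk-scale tests do and
do not establish.

## The procedure

Segmentation is sequential: a liver stage delineates the organ on
windowed axial slices, then a lesion stage works only on the liver
volume of interest. Each stage is an ensemble of four semantic
segmentation networks built from classification backbones (ResNet152,
ResNeXt101-32x8d, DenseNet201, InceptionV3) whose classifier heads are
removed and whose first convolution takes one grayscale channel. A
shared head design — atrous spatial pyramid pooling with a 1x1 branch,
three 3x3 atrous branches, and a global image-level branch, projected to
256 channels, dropout 0.5, and a final 1x1 projection to one score
channel — produces per-pixel logits, bilinearly upsampled to the slice
size.

The four per-network binary masks are merged by a weighted vote: a
pixel is foreground when `sum_i w_i P_i >= 1/2`. The weights are the
only trainable parameters of the fusion module and are fit by SGD with
momentum on pixel-wise binary cross-entropy of `sigmoid(P w)` against
the reference mask. The literal round-of-sigmoid form is retained behind
`fuse(..., rule = "sigmoid_round")`, but it cannot be the default: on
binary masks with positive weights, `sigmoid(x) > 1/2` is simply
`x > 0`, so any single network's vote would win — contradicting the
ensemble's purpose. The threshold form with ties resolved to foreground
makes two agreeing networks (at equal weights) sufficient, which is the
intended voting semantics.

### Assumptions

* Voxels are Hounsfield units; all soft-tissue contrast of interest
  lives in the −250..250 HU window (the default `WindowSpec`).
* Labels follow the LiTS convention 0/1/2; the liver-stage target is
  `labels >= 1` and the lesion-stage target `labels == 2`.
* One examination is a stack of axial slices; slice order is the
  alphabetical file order for DICOM series, and the slice axis of a
  NIfTI volume is taken from the affine (largest-spacing axis as a
  fallback).
* Lesions are hypodense relative to liver parenchyma, the premise of
  the lesion-stage contrast enhancement.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window | −250..250 | HU | soft-tissue window; fixes the `[0,1]` intensity scale |
| working side | 256 | px | training/inference slice size; balances memory and detail |
| output stride | 8 | — | late strides become dilation so features stay 32x32 at side 256 |
| atrous rates | 4, 8, 12 | — | chosen for 32x32 feature maps; a 3x3 kernel dilated by `rate >= side` degenerates to 1x1 (`atrous_validity()` warns) |
| head dropout | 0.5 | prob. | regularization of the projection layer, training only |
| liver lr schedule | 0.05, x0.95 every 10 epochs, 200 epochs | — | slow decay for training from scratch |
| lesion lr schedule | 0.1, halved each epoch, 20 epochs | — | fine-tuning from liver-stage weights; last-epoch rate 1.9e-7 |
| fusion training | lr 10, momentum 0.9, 5 epochs, batch 32, init 0.25 | — | the 4-parameter objective is tiny; the converged point is insensitive to the rate across roughly 1..15 |
| liver filter | 200 px distance, 1/8 area ratio | px | removes extrahepatic distractors (spleen/intestine-like) while never touching the largest region |
| lesion filter | 10 px minimum area | px | removes granularity/noise detections |
| CLAHE | 8x8 tiles, clip 0.01 of tile pixels | — | contrast-limited equalization; clip fraction maps to `EBImage::clahe(limit = clip * bins)` |

Post-processing thresholds are configurable (`pipeline_config()`)
because the empirical 200/8/10 values may presuppose a particular slice
resolution; the package applies them at the working side (256), where
masks are produced.

## Numerical choices

* **Resizing.** Bilinear interpolation for intensities, nearest
  neighbour for masks (preserving the binary alphabet). The bilinear
  operator is built explicitly as interpolation matrices with
  half-pixel centers, so a resize is two matrix products and its
  adjoint (needed in the head's backward pass) is the transpose. It
  agrees with `EBImage::resize` to machine precision, which the tests
  use as an independent cross-check.
* **Convolution.** Evaluated as a sum of per-tap GEMMs; verified
  against a direct nested-loop oracle over strides, dilations, pads and
  groups, and gradients are verified by central finite differences.
* **Batch normalization** is present structurally in every built
  network as a per-channel affine transform with fixed normalization
  statistics (identity at initialization); scale and shift are
  trainable, running-statistic tracking is not implemented. The
  equation-level block oracles exclude normalization by construction.
* **Initialization.** Kaiming normal with the ReLU gain,
  `sd = sqrt(2 / fan_in)`, for every convolution (head and backbone).
* **Ties and degenerate inputs.** Fusion ties at exactly 1/2 go to
  foreground. `dice()` defines empty-vs-empty as 1 (and one-empty as
  0), while the error-overlap matrix defines empty-vs-empty error sets
  as 0 — there "no shared error mass" is the informative reading, and
  its diagonal is 1 only for networks with at least one error. An
  all-zero slice passes through `fill_background_with_mean()`
  unchanged; such slices are dropped by the VOI crop anyway. A flat
  fusion objective (all-empty masks and references) returns the initial
  weights with a warning.
* **VOI coordinates** are 0-based, half-open on every axis.
* **Component connectivity** is 8 (diagonal bridges do not split a
  region), computed on a pixel-adjacency graph.

## Architecture geometry

Two geometry conventions coexist deliberately:

* The *canonical* builders reproduce each family's published geometry,
  including valid padding in the Inception stem. Consequently the stem's
  documented `35x35x192` output holds at the architecture's native
  299x299 input; at a 256 input the same stem arithmetically yields
  `29x29x192`, and the full canonical extractor `8x8x2048` at 299. The
  tests pin both.
* The *adapted* builders (output stride 8, the system's operating
  point) convert the last two stage transitions of the residual
  families to dilation, drop the average pooling of the second and
  third dense transitions, and rebuild the Inception stem with 'same'
  padding and no max pooling so that exactly three stride-2 operations
  remain. For every family the adapted in-plane extent is then exactly
  `ceiling(side / 8)` — a uniform contract the head relies on.

The dense block follows the standard concatenation (block input
included): that is the only reading under which DenseNet201's
1920-channel output arithmetic works. A strict mode that concatenates
only the four layer outputs is kept for the closed-form block oracle.

## The synthetic phantom

`generate_phantom()` emulates what the pipeline logic actually depends
on — intensity bands and topology, not anatomy: an air background
(−1000 HU), a soft-tissue body ellipse (40 HU), a bright spine-like
ellipse (400 HU), one connected liver ellipsoid (60 HU), darker lesion
spheres inside it (30 HU), an optional extrahepatic distractor at liver
intensity, and Gaussian noise (10 HU). Defaults are 64 slices of 256²
at 2.5 x 1 x 1 mm.

`generate_candidate_masks()` perturbs reference masks per network with
boundary jitter, random region misses and false blobs, independently
across networks — the situation the fusion stage exists for.

For end-to-end validation the networks are replaced by *oracle models*:
the liver oracle thresholds the smoothed slice in a parenchyma HU band,
requires local homogeneity (rejecting partial-volume rings around
bone), and fills enclosed holes (lesions belong to the liver mask); the
lesion oracle thresholds the equalized crop below a fixed dark level,
opens away the thin boundary halo left by bilinear cropping, and
discards border-touching components. The four oracles of each stage use
slightly different bands so their errors do not coincide.

What passing these tests shows: the windowing, VOI, fusion, filtering
and reassembly chain is geometrically and numerically correct, and the
training loop optimizes what it claims to. What it does not show:
segmentation accuracy on real CT — real parenchyma is not an intensity
band, and no desk-scale surrogate can stand in for trained networks on
clinical data.

## Problem sizes used by the test suite

Full-size backbones are forwarded once per shape contract (sides 256
and 299; side 128 for the stride invariant). Training behavior runs on
the tiny profile (reduced block counts and widths, same topology) at
side 32 with 8 slices and 2 epochs over 10 seeds. Fusion training
fixtures use 24–1536 slices of side 32–64; the learning-rate robustness
fixture uses identical slices so mini-batch gradients are deterministic
and the converged points can be compared at 1e-5.

## Known limitations

* No batch-statistic tracking in normalization layers; full-size
  training from scratch would converge differently than a
  batch-norm-tracking implementation.
* The DICOM codec covers uncompressed single-frame explicit/implicit VR
  little endian only — enough for CT series and the RGB overlay output,
  not for compressed transfer syntaxes or multi-frame objects.
* Pre-trained backbone weights are not shipped; initialization is
  Kaiming (externally supplied parameters can be loaded into the
  parameter nodes, but pre-training is out of scope).
* Post-processing thresholds were taken at the working resolution; at
  full 512² resolution they may need rescaling.
* The lesion stage inherits any liver-stage error: a missed liver
  region can never yield lesion detections (evaluation with reference
  liver masks is supported by passing a mask volume to
  `run_lesion_stage()`).
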