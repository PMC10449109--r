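---
title: "Pseudo-colorizing masked cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-colorizing masked cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudocell)
```

## The pretext task

Fluorescence microscopy supplies abundant unlabeled imagery but scarce
annotation. `pseudocell` implements a self-supervised pretext task for this
setting: a model receives a grayscale cell image whose input has been
partially masked, and must reconstruct a *pseudo-colorized* version of the
full, unmasked image. Two ingredients make the task informative:

1. **Pseudo-colorization.** A colormap lookup table maps each intensity to
   an RGB triple. With a pseudo-spectral map (`nipy_spectral`: a spectral
   map extended with black at the bottom and gray at the top), low
   intensities land mostly in the blue channel, medium intensities in
   green, high intensities in red — so reproducing the coloring forces the
   model to partition the image by intensity bands, a coarse approximation
   of semantic segmentation of cell topology. Plain autoencoding is
   recovered as the same code path with the `gray_identity` LUT.

2. **Padded masking.** Instead of the large 16 px patches covering 75% of
   a 224 px image used in masked-autoencoder practice, small 12 px patches
   (at 384 px input) are masked independently with probability 0.5, and
   every patch is surrounded by guaranteed-unmasked padding of a quarter
   patch width. Padding is *shared* between neighbouring tiles, so the
   tile stride is 15 px. No cell is ever fully hidden, and the longest
   masked run along any row or column is bounded by the patch size — the
   property that makes partially visible cells usable as reconstruction
   clues. Masked pixels are set to zero by default; a variant fills each
   masked patch with a common draw from U{0, 1} (`fill = "random01"`).

With shared padding the expected coverage of full tiles is
`0.5 * 144 / 225 = 32%` (the often-quoted one-third is approximate;
no literal reading of the 12/3 geometry yields exactly 1/3, and
`expected_padded_fraction()` enumerates the exact expectation for any
image size including partial border tiles). `calibrated_prob()` inverts
the geometry when a specific expected coverage is wanted.

The perceived-brightness curves used to characterize colormaps come from
the HSP color model, `B_p = sqrt(0.299 R^2 + 0.587 G^2 + 0.114 B^2)`;
`brightness_profile()` evaluates it over all 256 LUT entries.

### Quantization

LUTs are shipped as 256-entry CSV tables precomputed from the standard
published control points, and `apply_colormap()` uses nearest-index lookup
(`round(v * 255)`) rather than interpolation. The choice is pinned for
bit-reproducible targets; the LUT resolution and interpolation of upstream
implementations vary, so profiles are asserted qualitatively
(monotonicity, endpoints) rather than to many decimal places.

## The detection codec

Cells are represented by centroid, width and height. Training targets are
three dense maps at input resolution:

* **Centroid heatmap** — each cell is drawn as a filled ellipse (semi-axes
  w/2, h/2, value 1) and smoothed with a normalized box filter with kernel
  `(w %/% 1.5, h %/% 1.5)`. The raw floor division can produce even kernel
  sizes, which would shift the smoothed peak half a pixel off the
  centroid; kernels are therefore bumped to the next odd integer.
  Overlapping cells combine by per-pixel maximum.
* **Size maps** — a rectangle of half the cell's size at the cell center
  carries `w / W` and `h / H` (dimensions relative to image size). Where
  rectangles overlap, the larger cell wins; this precedence is arbitrary
  but deterministic.

Decoding thresholds the heatmap at a strict `> 0.75`, labels 8-connected
components, drops components under 4 px (single-pixel noise suppression),
computes each blob's centroid from raw image moments
(`M10/M00, M01/M00`), and reads the cell size off the size maps at the
rounded centroid pixel — no neighbourhood averaging. Boxes are emitted as
top-left corner plus width and height. Because only the `> 0.75` level
set matters, decoding is invariant to any monotone rescaling of the
heatmap that preserves it.

For scenes whose cells are separated by at least their own diameter the
codec round-trips exactly: 100 seeded scenes recover every cell with
centroid error at most 1 px and size error at most one quantization unit
(the acceptance suite measures typically zero error).

## Model

The detector is a hybrid fully convolutional network preceded by a
slice-context block:

* **ContextBlock** — for 3D stacks analysed slice-wise, each neighbouring
  slice passes through a 3x3 convolution with 10 filters and a 1x1
  depth-fusing convolution; the result is merged with the current slice by
  an elementwise multiply-accumulate and squashed with a sigmoid. Channel
  2 carries the untouched current slice. Branch parameters are per-branch
  (the two conv stacks in the fusion equation are distinct); an optional
  shared-parameter mode exists for symmetry experiments. 2D images pass
  the same slice into all three inputs, yielding three learned views.
* **Backbone / neck / heads** — the full-scale design composes an
  EfficientNetV2S-class backbone with an attention-augmented neck and two
  upsampling heads. Those widths are not published; this package bundles
  `test_tiny`, a compact strided CNN (~21k parameters) with a
  convolutional neck, one shared upsampling trunk and two 1x1 output
  convolutions, which preserves every architectural contract (resolution
  in = resolution out, sigmoid heads, swappable top, freeze modes) at a
  size where CPU training finishes in seconds per epoch. Parameter-count
  parity with the full-scale model (e.g. the heads being 17% of
  parameters) is explicitly not asserted.

The top layer is the only part swapped between pre-training (3-channel
sigmoid reconstruction) and detection (1-channel sigmoid heatmap +
2-channel sigmoid sizes); `swap_top()` preserves all other parameters
bit-exactly. `set_freeze()` expresses the three training procedures:
fine-tuning (`none`), head evaluation (`backbone_and_neck` frozen) and
backbone evaluation (`backbone` frozen).

### The numerical engine

Training runs on a compact self-contained CNN engine (im2col convolutions,
manual reverse-mode gradients, Adam) written for bit-reproducible
desk-scale experiments; analytic gradients are verified against finite
differences in the test suite. Two numerical choices matter:

* hidden activations are leaky ReLU (slope 0.1) — at the small widths of
  `test_tiny`, plain ReLU lets aggressive learning rates kill entire
  channels and freeze training;
* sigmoid logits are clamped to [-30, 30] so saturated outputs keep a
  nonzero gradient instead of rounding to exactly 0 or 1;
* the heatmap head's bias is initialized to -2, the negative-prior
  initialization customary for centroid-heatmap detectors: the
  mostly-background heatmap starts near its base rate, which prevents
  short training runs from collapsing into the constant-background local
  optimum.

Checkpoints are JSON with a format-version field and 17-significant-digit
numbers, so a save/load cycle is bit-exact.

## Losses and metrics

Detection training minimizes `L_total = L_heatmap + 0.5 L_height +
0.5 L_width`, each term a Huber loss (delta 1, mean reduction over the
full maps — zeros outside the size rectangles included, matching the
map-regression formulation). Pre-training minimizes pixel-wise MSE over
*all* pixels (the objective reconstructs seen and unseen parts alike); a
masked-only option exists.

Reconstruction quality is summarized by a *global* SSIM: means, variances
(population convention) and covariance over the whole input, with
stabilizers `(0.01 L)^2` and `(0.03 L)^2` — not the windowed variant.
RGB inputs are scored per channel and averaged. Heatmap quality uses a
two-class mIoU after thresholding both maps at 0.75; a class absent from
both prediction and ground truth contributes IoU 1 (the degenerate
no-blob case is otherwise undefined). Box AP is delegated: detections and
ground truth are exported as standard COCO JSON for any COCO evaluator.

## Synthetic scenes

The generator emulates fluorescence microscopy of simulated nuclei: dark
background (level 0.05), bright elliptical cells (semi-axes 5-15 px at
384 px, intensities 0.55-1), Gaussian-blurred borders (sigma 1 px),
additive Gaussian read noise (sigma 0.02) and rejection-sampled centroids
with a 40 px minimum separation. The 64 px smoke-scale variant
(`smoke_scene_spec()`) scales cell size and separation proportionally.
3D stacks use ellipsoids whose cross-sections shrink toward the stack
borders, reproducing the size-vs-depth structure of 3D cell data.
Annotations derive from the realized instance mask, so image, mask and
boxes are mutually consistent by construction.

What the generator does *not* emulate: Poisson shot noise, optical PSFs,
texture within cells, cell-to-cell contact and overlap, illumination
gradients. Passing tests therefore demonstrate the correctness of the
codec, masking and training mechanics on idealized data, not detection
performance on real microscopy.

## Training pipelines and the smoke-scale experiments

`pretrain()` and `train_detect()` follow the reference optimizer setup by
default: Adam, learning rate 1e-4 reduced on plateaus by a factor of 10
to 1e-6 (patience 5 epochs — the patience is unpublished and
configurable), 75 epochs for pseudo-color pre-training, 50 for plain
autoencoding and for detection, batch size 8 at 384 px and 32 at 64 px.
Masks corrupt only the input, never the target, and are redrawn each
epoch.

The package's own experiments run at desk scale: 64 px scenes, the
`test_tiny` backbone, lr 1e-3 with batch size 4 (a sweep during engine
bring-up showed 1e-3 is the largest stable rate at this model size; 1e-4
learns the same curves more slowly). Problem sizes are 50-200 scenes and
2-5 epochs: enough for the three checks the suite makes — pre-training
MSE falls within two epochs; five epochs of detection training exceed the
0.5 mIoU of an empty prediction; and over three seeds, head evaluation
from a pseudo-color+masking pre-trained model reaches a mean training
mIoU at least as high as from random initialization. The last check is a
directional tendency at smoke scale with three seeds, not a reproduction
of full-scale benchmark tables; run-to-run spread is large and only the
mean ordering is asserted.

## Known limitations

* The bundled backbone is deliberately tiny; no claim is made about
  absolute detection quality.
* AP is exported, not computed; an external COCO evaluator is required
  for AP numbers.
* The padded-mask mean coverage at the default geometry is 32%, not the
  sometimes-quoted one-third (see above).
* `augment()` covers flips, 90-degree rotation and restricted crops; the
  elastic/perspective/shift-scale-rotate family used for offline dataset
  expansion is out of scope.
* Training is single-threaded by design for reproducibility; determinism
  across BLAS implementations is expected but only bitwise-verified
  within one platform.
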