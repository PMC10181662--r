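---
title: "seedHSI: models and methods"
author: "seedHSI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedHSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedHSI)
```

## Scope

seedHSI processes hyperspectral image (HSI) cubes of crop-seed panels —
the motivating system is rice (*Oryza sativa*, cv. Kitaake) grown under
high day and/or night temperature treatments — and classifies seeds two
ways: whole-seed sub-cubes through a 3-D convolutional network, and
individual pixel spectra through a deep fully-connected network. Around
those two classifiers the package provides the full working pipeline:
cube I/O, reflectance calibration, segmentation, phenotype descriptors,
evaluation metrics, maps and embeddings, plus a synthetic panel generator
that makes every stage testable without access to proprietary sensor data.

The reference sensor is a line-scan spectrograph sampling 597.21 nm to
1703.93 nm at 4.14 nm, i.e. 268 bands, with scenes of 1250 x 450 pixels.
Those constants are defaults, not assumptions: every function takes an
explicit `WavelengthGrid`.

## Data model

A `Hypercube` is a `rows x cols x bands` array with axis order fixed
throughout the package, a uniform `WavelengthGrid`, and provenance
metadata including a `calibrated` flag. Band indices are 1-based, as is
idiomatic in R; `bandIndex()` maps wavelengths to the nearest band with
exact midpoints rounding toward the lower index, so the mapping is
deterministic and invertible on grid points.

On disk, cubes are ENVI (text header plus flat binary, all of BIL/BIP/BSQ
accepted and normalized on read) or HDF5 (`/data`, `/wavelengths_nm`,
metadata as attributes). Storage is float32. ENVI wavelength lists are
written with two decimals — the precision at which the sensor grids this
package models are specified — so grids with finer precision should
prefer HDF5, which stores the grid exactly.

## Reflectance calibration

Raw intensity is converted to reflectance with the classical white/dark
reference model:

$$I_c = \frac{I - I_d}{I_w - I_d}$$

where $I_w$ is a white (100% reflectance, e.g. Teflon tile) reference and
$I_d$ a dark (shutter closed) reference. Properties that follow directly —
affinity in $I$, invariance to a common gain and offset, exact recovery of
$\alpha$ for $I = \alpha I_w + (1-\alpha) I_d$ — are asserted as tests.

Design choices where the model itself is silent:

- **Reference geometry.** References may be full-frame or a one-line
  column profile (the line-scan convention); profiles are broadcast
  across rows.
- **Degenerate denominators.** $I_w = I_d$ (dead pixels) is an error by
  default, listing affected bands. An optional epsilon guard
  (`|I_w - I_d|` below `1e-6` of the white dynamic range) masks such
  elements to 0 with a reported count instead, since isolated dead pixels
  are routine in practice.
- **Clipping.** Output is clamped to `[0, 1.2]` by default: specular
  glints legitimately exceed the white tile slightly, but unbounded
  values destabilize network training.
- Calibrating an already-calibrated cube is refused outright.

Replicate reference frames can be averaged with `averageReference()`; the
pipeline treats this as optional because acquisition protocols differ.

## Segmentation

The seed/background separation is deliberately parameter-light: a scalar
score image (mean reflectance over a configurable band window, default
all bands), Otsu's threshold, binary closing (disc radius 2), 8-connected
component labeling, then filters. Defaults: minimum area 50 px; regions
touching the frame edge are discarded, because clipped seeds bias every
shape descriptor. Regions are ordered by bounding-box (rowMin, colMin) so
results are deterministic. Touching-seed splitting (watershed) is out of
scope; the generator and the intended panel layouts keep seeds disjoint.

Extraction crops each region's bounding box, zeroes non-mask pixels, and
centres the crop in a canonical chip (default 64 x 32) with zero padding.
Oversized regions are band-wise bilinearly resized, aspect preserved; the
spectral axis is never resampled. Each chip records the panel coordinates
of its origin so pixel predictions can be painted back into the frame.

## Phenotype descriptors

The shape model is an ellipse derived from the region boundary:

- the *diameter* is the maximum pairwise distance between boundary pixel
  centres (computed on the convex hull; the independent test oracle is
  the full $O(n^2)$ scan), ties broken by smallest index pair;
- $a$ is half the diameter, oriented along the achieving pair; $b$ is
  half the extent of the mask projected on the perpendicular — the
  "perpendicular extent" reading is our operationalization, since a
  minor axis is not otherwise defined for a raster region;
- eccentricity $\sqrt{1-(b/a)^2}$, area $\pi a b$, perimeter
  $p = \pi(a+b)$, compactness $p^2/A$, roundness $4\pi A/p^2$.

The perimeter $\pi(a+b)$ is a deliberately simple ellipse approximation
kept as the package's primary definition so that the identity
$\text{roundness} \times \text{compactness} = 4\pi$ holds exactly and a
circle attains compactness $4\pi$, roundness 1. Ramanujan's approximation
is available behind `perimeterMethod = "ramanujan"` for users who want a
tighter perimeter; it breaks the identity by construction.

Mean intensity reduces bands first (per-pixel band average), then
averages over masked pixels; the reduction order matters for nothing
linear but is stated and tested. `mean_spectrum` is the per-band masked
mean. A collinear region gets $b = 0$ and an explicit degenerate flag
rather than a silent boundary value.

## Seed-level 3-D CNN

The classifier input is one whole seed chip; the spectral axis is mapped
to the convolution depth $D$ (it is the informative axis), the chip's
H x W are the spatial axes, and the input channel count is 1. Valid
(no-padding) 3-D convolution is

$$O_{c',i,j,k} = \sum_{c}\sum_{d}\sum_{h}\sum_{w}
  I_{c,\,i+d,\,j+h,\,k+w}\; K_{c',c,d,h,w} + b_{c'}$$

with ReLU and 3-D max pooling (stride = window; border windows are
clipped, which for a maximum is identical to replication padding). The
topology is two conv blocks, flatten, one fully-connected ReLU layer, and
a softmax output. Unstated hyperparameters were fixed once at CPU-friendly
values: block 1 with 8 channels and kernel (7, 3, 3), block 2 with 16
channels and kernel (5, 3, 3), both pooled (2, 2, 2); FC width 64; Adam
(learning rate 1e-3), cross-entropy, 50 epochs, batch 8. The
convolution/pooling forward and backward passes are implemented in C++
within the package and are checked elementwise against independent
nested-loop oracles in the tests.

As printed, the convolution formula sums over both $c$ and $c'$, which
would double-count output channels; the implementation uses the standard
per-output-channel sum over input channels.

Protocol: stratified 80/10/10 train/validation/test split with
largest-remainder rounding (40 seeds per class give exactly 32/4/4;
remainder ties resolve train, then val, then test). Augmentation tops
each class up to a target (40 by default in the study design) using
label-preserving spatial transforms of training originals only —
horizontal/vertical flips, 180-degree rotation, shifts up to 2 px —
leaving spectra untouched. One master seed drives the split, the
augmentation draws, weight initialization and batch shuffling, so a run
is reproducible bit-for-bit on a single thread.

## Pixel-level DNN

Each masked seed pixel contributes its full spectrum as one row of a
pixels x bands matrix. The network is an input layer (one unit per
band), 12 ReLU hidden layers and a softmax output, trained with Adam on
categorical cross-entropy. The depth is part of the design being
emulated; the widths are not stated anywhere, so the package defaults to
a taper (256, 256, 128, 128, 128, 64, 64, 64, 32, 32, 32, 16) chosen to
keep CPU training tractable. Per-band standardization (training-split
mean and standard deviation) is applied before the first layer and
stored with the model; it is invertible bookkeeping, not a modeling
choice, but without it the deep stack optimizes poorly.

The 70/30 train/validation pixel split is performed within each seed
("70% of the pixels of each seed" being read per-seed; a global split is
available by flag), so every seed is represented on both sides. Seeds
with fewer than two pixels go wholly to training, with a message. Class
imbalance is handled by plain cross-entropy — no reweighting — matching
the emulated design's silence on the issue.

## Evaluation

`multiclassReport()` computes, from a truth x prediction confusion
matrix: per-class one-vs-rest precision, recall and F1 with macro and
support-weighted averages; overall accuracy OA = trace/total; average
accuracy AA = mean per-class one-vs-rest accuracy
$(TP+TN)/(TP+TN+FP+FN)$; and Cohen's kappa $(P_o-P_e)/(1-P_e)$ with
$P_o = OA$ and $P_e$ from the marginal products. The binary formulas are
the base definitions; the multi-class generalization above is the
standard one and collapses exactly to them at $k = 2$ (asserted in
tests). Zero-denominator metrics are reported as 0 with an explicit
undefined flag rather than NaN, keeping CSV/JSON output stable.

Classification maps paint per-pixel predictions back into the panel frame
(background sentinel 0) with a colour-blind-safe default palette and a
JSON legend sidecar. For visual cluster structure the package reduces
spectra to their first 50 principal components (centred, unscaled) and
embeds them in 2-D with t-SNE (perplexity 30, fixed seed); "components"
rather than raw bands is the reading adopted where the two could be
confused, with the component count reduced automatically (and a warning)
for small n.

## Synthetic data generator

The generator defines the package's study conditions. Each treatment
class has a mean reflectance spectrum built from a smooth shared baseline
(0.35 plus a broad bump, matching the unstructured NIR reflectance of
starchy seed tissue) plus three class-specific non-negative Gaussian
bumps whose amplitudes scale linearly with a `separation` parameter
(default 1: amplitudes 0.05-0.10 reflectance units, giving clearly
separable but overlapping spectra). Exposure duration multiplies the
class deviation by $1 + 0.002\,(h - 204)$ — a within-class shift an order
of magnitude smaller than the between-class differences, mirroring how
exposure subclasses are harder to separate than treatments. Pixel noise
is i.i.d. Gaussian per pixel-band, default sd 0.02 reflectance units, a
typical NIR line-scan noise floor.

The sensor model writes raw counts as
`dark + reflectance * (white - dark) + noise`, with the white reference a
smooth lamp spectrum peaking near 85% of a 12-bit range and the dark
reference a constant offset — so the Shafer calibration inverts the
generator exactly at zero noise, and the noise seen after calibration has
exactly the configured reflectance-unit sd. Seeds are ellipses placed on
a jittered cell grid that guarantees at least 2 px of clearance
(overlapping specifications are rejected, not silently fixed).

What the generator does **not** emulate: spatially correlated noise and
illumination non-uniformity, within-seed texture (embryo/endosperm
structure), touching seeds, specular glints, and biophysically realistic
absorption features. Passing the class-recovery tests therefore shows the
pipeline is correct and the architectures can learn spectral class
structure at realistic noise; it does not certify accuracy figures on
real rice panels.

## Problem sizes and numerical choices

Tests and the acceptance script run at reduced scale, chosen as the
package's own validation conditions: seed chips of 16 x 16 or 32 x 32
pixels with 32 bands, roughly 2000 masked pixels per class for the
pixel classifier (10 seeds per class), and 40 chips per class for the
3-D CNN, matching the study's per-class image count. At those sizes the
pixel network reaches held-out accuracy at or near 1.0 and the 3-D CNN
reaches its accuracy floor (>= 0.90) within the default 50 epochs. A
label-permutation negative control trained identically collapses to
chance, confirming the accuracy comes from class structure rather than
leakage.

Numerical details fixed by fiat and documented here: nearest-band ties
round down; probability ties in prediction resolve to the lowest class
index; largest-remainder ties resolve in split order; He initialization
for all weights; Adam with beta = (0.9, 0.999), eps = 1e-8; softmax is
computed with the row-max subtracted; cross-entropy clamps probabilities
at 1e-12. Training determinism holds for a fixed seed and thread count —
the BLAS used for the dense layers must be single-threaded for
bit-identical replay.

## Known limitations

- The segmentation threshold is global; panels with strong illumination
  gradients would need the band-window or an external threshold.
- Watershed splitting of touching seeds is not implemented.
- The 3-D CNN trains on CPU at small chip sizes; full sensor-scale chips with
  268 bands are supported but slow.
- The generator's limitations above bound what synthetic validation can
  claim about real data.
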