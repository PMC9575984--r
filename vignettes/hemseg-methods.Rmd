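---
title: "Methods: hemorrhage segmentation and volumetry with hemseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemorrhage segmentation and volumetry with hemseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

hemseg implements a complete quantitative pipeline for intracerebral
hemorrhage (ICH) on non-contrast head CT: synthetic phantom generation,
preprocessing, a 2-D attention-gated U-Net with a space-to-depth focus
encoder branch, training, segmentation metrics, and volumetry with
method-agreement statistics. Everything is testable end-to-end on built-in
phantoms; no clinical data or download is required.

### The segmentation network

The network is a standard 2-D U-Net (double 3x3 convolution + ReLU per
level, 2x2 max pooling, bilinear upsampling, sigmoid head) with two
additions:

* **Focus branch.** At every encoder downsampling the incoming feature map
  `(H, W, C)` is also passed through a lossless space-to-depth
  rearrangement into `(H/2, W/2, 4C)` — the four stride-2 phase sub-grids
  stacked along channels — followed by a 3x3 convolution to `max(1, C/2)`
  channels and ReLU. This branch is concatenated with the max-pooled path
  before the next level's convolutions, so fine, low-contrast detail (small
  hemorrhage foci) survives downsampling. Because pooling discards values
  while space-to-depth is a bijection, the fused input retains the complete
  pre-pooling signal.
* **Attention gates.** Each skip connection is reweighted before
  concatenation: the skip and the upsampled decoder features are projected
  by 1x1 convolutions, combined (additively by default; channel
  concatenation is available via `ag_mode = "concat"` since the mechanism
  is sometimes described as feature splicing), passed through ReLU, reduced
  to one channel, and squashed by a sigmoid into an attention map
  `alpha in (0, 1)`; the skip is multiplied by `alpha`. Gated features can
  therefore never exceed the raw skip in magnitude.

Turning the focus branch off yields the attention U-Net ablation
(AttUNet); turning both off yields a plain U-Net. Several wiring details
are deliberately parameterized because they are genuinely open design
choices: the phase order of the focus rearrangement is fixed (even/even,
even/odd, odd/even, odd/odd) purely for determinism — any fixed order is
equivalent up to learned weights; the focus branch is fused at every
downsampling by default with a single-entry "stem" mode available
(`focus_entry`); the `C/2` focus output rule is clamped to at least one
channel because the raw image has a single channel; channel widths double
per level from `base_channels`.

### Preprocessing

CT volumes are resampled in-plane to a square matrix (bilinear for images,
nearest-neighbour for masks so labels stay binary), reduced to a fixed
number of axial slices, then windowed to the hemorrhage range
[-60, 140] HU and mapped linearly onto [0, 1]. The normalization target
range is a convention; [0, 1] is used throughout. Slice selection keeps
the contiguous window maximizing the summed per-slice head score (mean
intensity excess over an air threshold of -500 HU): a deterministic,
testable proxy for the manual removal of chest/abdomen slices. Stacks
shorter than the target are padded with air slices split across both ends
(extra slice at the top), and the padding is recorded in the volume's
metadata.

### Volumetry

The reference volume is voxel counting: `V = sum_i X * Y * T * W_i` over
slices, reported in mL. The clinical comparator is the Coniglobus
(ABC/2) estimate, automated from a mask: on the largest 6-connected
component, the slice of maximal lesion area is found (ties broken at the
lowest slice index); `A` is the maximal distance between lesion-pixel
*corner* points on that slice (caliper-style, edge-to-edge, matching how
a clinician reads a diameter off the screen); `B` is the extent of the
corner points projected perpendicular to the `A` chord (equal to the
longest perpendicular chord for convex lesions); `C` is the number of
lesion slices times the slice thickness. The corner-point (rather than
center-point) convention is the one behind all worked examples: a 10 x 20
pixel rectangle at 1 mm pixels measures A = sqrt(500), B = 400/sqrt(500),
and with three 4-mm slices gives exactly 2.4 mL.

For an axis-aligned ellipsoid with full diameters A, B, C the ratio of
ABC/2 to the true volume pi*ABC/6 is 3/pi (about 0.955), so even perfectly
ellipsoidal lesions are slightly under-read; non-ellipsoid (lobulated)
lesions are measured much less accurately, which the phantom experiments
reproduce.

Because the clinical source of published Coniglobus readings (manual
calipers vs. masks) is not knowable from outside, the package automates
the measurement from masks and documents this as its convention.

### Agreement statistics

Method agreement against the reference volume uses the two-way
random-effects, absolute-agreement, single-measurement intraclass
correlation ICC(2,1), computed from the ANOVA mean squares of the n x 2
table — the absolute-agreement variant is recorded in the output because
the variant choice materially changes the value (a constant shift lowers
ICC(2,1) but not a consistency ICC). Ordinary least squares of method
volume on reference volume supplies slope, intercept and R^2.

### Segmentation metrics

Dice, IoU, sensitivity and PPV come from voxel confusion counts pooled
over the full 3-D stack; per-case values are averaged unweighted over the
cohort. When predicted and reference masks are both empty all four
metrics are defined as 1 and flagged degenerate; a 0/0 against a
non-empty counterpart is NA and excluded from means with a reported
exclusion count. Evaluation is per-case and mm-scaled (not per-slice):
the surface distance is only meaningful with physical spacing, and one
value per case is the only spacing-aware reading of cohort tables.

HD95 uses surface voxels (6-connectivity: a lesion voxel with a
face-adjacent background neighbour, or on the array boundary), scaled to
mm, and nearest-neighbour directed distances. The default `percentile95`
mode takes the larger of the two directed 95th percentiles
(linear-interpolation percentile, R type 7), which actually suppresses
outlier surface points; the literal "0.95 x Hausdorff" reading is kept as
`scaled95` because it is sometimes stated that way even though a global
scaling cannot remove outliers. Both modes are symmetric in their
arguments.

## The phantom generator

Each phantom is a head model — air background (-1000 HU), an elliptical
brain (30 HU, semi-axes 40%/40%/45% of the field of view) inside a thin
skull shell (1000 HU) — containing a hyperdense lesion at 70 HU, inside
the [-60, 140] window, with additive Gaussian HU noise (default SD 5,
clipped to plausible HU). Geometry defaults mirror the targeted
acquisition regime: 512 x 512 matrix, 40 slices, 4.0 mm slice thickness,
0.45 mm in-plane pixels (in-plane spacing is a free parameter since
clinical series vary).

Three shape families span the ellipsoid / non-ellipsoid contrast:
a single rotated ellipsoid; a lobulated union of 2-4 overlapping rotated
ellipsoid lobes; and two disjoint foci. A voxel is labelled lesion exactly
when its centre lies inside the geometry — the same rasterization a
slice-wise expert delineation produces. Ground-truth volumes are exact
(closed form) for ellipsoids and computed by 4x-per-axis supersampled
voxelization over the lesion bounding box otherwise; on the test sphere
(radius 10 mm at 0.5 mm isotropic) the voxel-count volume agrees with the
closed form to well under 2%.

What the phantoms deliberately do **not** emulate: real anatomy
(ventricles, midline, bone texture), partial-volume blur, beam-hardening
artefacts, and the intensity overlap between hemorrhage and adjacent
structures that makes clinical segmentation hard. Tests passing on
phantoms therefore validate the *software* — geometry, arithmetic,
training mechanics — not clinical performance.

## Training protocol

RMSprop (squared-gradient decay 0.99, epsilon 1e-8), initial learning
rate 1e-5, 40 epochs, batch size 2, cases split 7:1:2 by case (floor /
floor / remainder — 1,027 cases split into 718/102/207) with slices
pooled across training cases and reshuffled each epoch. Slices with empty
masks are kept: with 40-slice stacks most slices contain no hemorrhage
and the network must learn absence. The learning-rate trigger multiplies
the rate by 0.1 whenever the best validation loss fails to improve
strictly for two consecutive epochs, and the stall counter then resets;
"failure to converge" is interpreted as this stalled-best rule, and 0.1
is the conventional step factor. When the trigger fires, training resumes
from the best checkpoint at the reduced rate (reduce-on-plateau with
best-weight restore; the optimizer state is reset) — without the restore,
RMSprop's scale-free steps let a stalled run drift irreversibly into the
all-background attractor before the smaller rate takes effect. The
checkpoint criterion is validation Dice, the task metric; the trigger
still watches the validation loss.

The loss is soft-Dice (smoothing 1) plus mean binary cross-entropy — a
standard pairing for imbalanced binary segmentation that vanishes in the
perfect-fit limit; the loss choice is a package decision as no specific
loss is mandated by the protocol it follows. Inside the trainer the
batch objective applies the per-slice soft-Dice term only to slices whose
reference mask is non-empty: on an empty-target slice the Dice ratio is
degenerate (0/0 up to smoothing) and acts purely as a shrinkage penalty,
which at phantom foreground fractions (about 1-2% of voxels) drives the
optimizer into predicting empty everywhere; absence is learned through
the cross-entropy term instead. Relatedly, the sigmoid head's bias is
initialized at the logit of a 5% foreground prior, the standard
initialization for rare-foreground detection, so training does not begin
with a destructive collapse phase from 50% predicted foreground.
`loss_fn()` itself keeps the plain textbook definition for any single
prediction/target pair.

Training is single-process and CPU-capable; all stochasticity (weight
initialization, shuffling, phantom noise) is governed by explicit seeds,
so runs are bit-reproducible on one platform.

## Numerical choices and scaled problem sizes

* Probabilities are clamped to [1e-7, 1 - 1e-7] inside the cross-entropy.
* Thresholding uses `>=`, so a probability exactly at 0.5 is foreground.
* Ties in maximal-area slice and head-window selection resolve to the
  lowest index.
* Gradients of every layer are hand-derived and verified against central
  finite differences in the test suite.

The demonstration experiments run at desk scale, chosen once as the
smallest sizes at which each phenomenon is measurable: the learning-sanity
experiment trains a depth-3 / base-16 network on 20 ellipsoid phantoms of
14 slices at 64 x 64 (2.5 mm pixels, 4 mm slices, lesion semi-axes
14-22 mm — volumes of roughly 11-45 mL, matching the clinical hemorrhage
range of about 33 +/- 23 mL when scaled to the 64-pixel field of view)
for 15 epochs at learning rate 3e-4 — the published rate of 1e-5 is tuned
to a 718-case GPU regime and is far too small to move a freshly
initialized network within 15 epochs of a 14-case cohort, so the rate is
scaled while the optimizer, batch size, trigger and split are kept; the
shape-bias experiment compares 20 ellipsoid against 20 lobulated phantoms
at 128 x 128 x 20 (1.8 mm pixels); the Coniglobus ratio check uses a fine
axis-aligned ellipsoid at 0.5 x 0.5 x 1 mm. Headline clinical values
(Dice 0.908, ICC 0.997) require the original 1,027-patient cohort and are
out of scope; the package instead verifies every formula, contract and
qualitative phenomenon at phantom scale.

## Known limitations

* No DICOM reader: cases must arrive as NIfTI (the usual research
  interchange); spacing is taken from the NIfTI header.
* The 2-D slice-wise model has no through-plane context; this matches the
  design it follows but limits very thin lesions.
* The automated Coniglobus B (perpendicular projection extent) can exceed
  the longest perpendicular chord for strongly concave single slices.
* Training on one CPU is practical only at phantom scale; the
  implementation favours correctness and reproducibility over speed.
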