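---
title: "Attribute-augmented left-femur segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribute-augmented left-femur segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(femaug)
```

## The problem

In radiotherapy planning for lower-abdominal cancers, organs at risk such
as the femurs must be delineated on every CT slice. The femur is a paired
organ with attenuation nearly identical to its contralateral twin, so a
segmentation model that sees only pixel intensities has no direct way to
tell *left* from *right* — especially since the patient's lying posture
(supine or prone) flips which side of the image the left femur occupies.
`femaug` implements a segmentation pipeline that addresses this with two
preprocessing ideas: cropping to an automatically located femur bounding
box, and *attribute augmentation* — appending a constant column to each
slice that encodes the lying posture as a small 8-bit coefficient.

## Pipeline

### Window leveling

CT voxels arrive in Hounsfield units (HU). A display window `(WL, WW)`
maps the range centered at `WL` of width `WW` onto 8-bit grayscale:

    HUmin = WL - 0.5 - (WW - 1)/2
    HUmax = WL - 0.5 + (WW - 1)/2
    y     = ((x - (WL - 0.5))/(WW - 1) + 0.5) * (ymax - ymin) + ymin

with hard clipping outside `[HUmin, HUmax]` and round-half-up
quantization (8-bit PNG export requires integers; the quantization rule
is our choice, as is treating out-of-ramp values by saturation rather
than wrap-around — saturation is what the designated `ymin`/`ymax`
values imply). The published formula for `y` can be parenthesized in
more than one way; the grouping above is the only one consistent with
the stated saturation values (100 HU maps to 0 and 499 HU to 255 under
the bone window `WL = 300, WW = 400`). Two windows are used: the bone
window (300/400) for localization and a soft-tissue contrast window
(120/336) for the images the model consumes.

### Histogram-projection localization

On each bone-windowed slice, the vertical projection sums every column
(and the horizontal projection every row), divided by a scaling constant
`Sc = 100`. Since only bone survives the bone window, the first and last
indices at which a profile reaches a plane-specific threshold bracket
the femur pair. Per scan:

* every axial slice contributes x and y extents, every coronal slice
  x and z, every sagittal slice z and y;
* slices whose profiles never reach the threshold are skipped;
* per axis, the candidate `lo` values are averaged and floored, the `hi`
  values averaged and ceiled, over all contributing slices of a plane;
* the two plane-level means that see each axis are merged by **covering
  union** (smallest `lo`, largest `hi`).

The covering union is a deliberate design decision for the one point the
procedure leaves open (how to merge planes that disagree): each plane
produces a conservative estimate, and the box exists to *cover* the
organ for cropping, so the union is the only merge that preserves that
guarantee.

**A known limitation of extent averaging.** Averaging per-slice extents
is only faithful for targets whose per-slice extents are homogeneous.
A localized protrusion (e.g. a femoral head bulging beyond the shaft)
creates grazing slices whose short extents drag the averaged coordinate
*inside* the organ; no threshold choice fixes this, because raising the
threshold merely relocates the grazing band. The synthetic phantoms are
therefore built near-prismatic (see below), and at clinical scale the
generous fixed-size crops absorb the residual under-coverage.

Thresholds are stated on the `Sc`-scaled profiles. The clinical values
(50 axial, 5 coronal/sagittal) presume 512 x 512 slices; profile sums
scale with the amount of cortical bone crossed, so the desk profile uses
2 (axial — accepts any column containing bone, still well above the
windowed-noise floor) and 25 (coronal/sagittal — about ten bone pixels,
keeping only slices that cross the shaft solidly).

### Cropping and attribute augmentation

Crops are fixed-size windows (clinical: 360 x 200 axial pixels) centered
on the located box, padded with the grayscale floor where they leave the
field of view — no resampling, so image quality is untouched. The
posture attribute is then appended as one constant column in raw 8-bit
units. Three coefficient scales exist: small (1 supine / 2 prone),
large (5/10), excessive (10/20); prone always receives the larger value
because prone positioning is the rarer, geometry-altering case. Eight
dataset categories cross cropping with augmentation: F-I (neither),
F-II (crop only), F-III/IV/V (crop + small/large/excessive), F-VI/VII/VIII
(no crop + small/large/excessive).

Ground-truth masks are cropped identically but never receive the
attribute column; at the attribute position the model is trained toward
background. Whether non-axial planes should also be augmented is not
fixed by the procedure; the implementation augments whatever plane it
emits (axial by default) — the column is a scan-level covariate, not an
axial-specific one.

### The segmentation model

A five-level U-Net: each contraction level applies two 3 x 3
same-padding convolutions with ReLU and one 2 x 2 max pool (resolution
halves, channels double, 64 at the first level in the reference
configuration); the expansion path mirrors it with 3 x 3 stride-2
transposed convolutions, skip concatenations, and double convolutions; a
final 1 x 1 convolution plus logistic sigmoid yields per-pixel
foreground probabilities, thresholded at 0.5 (ties to foreground — an
explicit tie rule so the behavior is reproducible). Inputs must be
divisible by 16 in both dimensions; the reference input is 352 x 208,
reached from the 360 x 200 crops by center padding rows and center
cropping columns, with offsets recorded so predictions map back to the
source geometry exactly (a genuine requirement: 360 x 200 itself is not
16-divisible).

Training minimizes pixelwise binary cross-entropy with Adam at learning
rate 0.001 (reference: up to 5000 epochs). Early stopping monitors
validation IoU with a patience of 50 epochs and restores the
best-validation weights. Weights are initialized with fan-in-scaled
Gaussians from the run seed; batch size is configurable (the optimizer
averages gradients over each mini-batch). Scans are split 60:20:20 at
scan level (floor sizes, remainder to training; 120 scans give
72/24/24), and one split is shared across all eight categories so
comparisons are paired.

The layer forward/backward passes are implemented in C++
(RcppArmadillo) as im2col/col2im GEMM reductions; the analytic gradients
are verified in the test suite against finite differences. One numerical
subtlety: with zero-initialized biases, feature-map regions whose entire
receptive field is zero sit *exactly* on the ReLU kink, where a
symmetric finite difference reports slope 1/2 while backpropagation uses
the standard subgradient 0 — the gradient test therefore jitters biases
off zero.

### Evaluation

Per scan, predicted slice masks are reassembled into a volume and scored
against ground truth with the Dice similarity coefficient
`DSC = 2|A∩B| / (|A| + |B|)` and intersection over union
`IoU = |A∩B| / |A∪B|` (both defined as 1 when prediction and truth are
empty — agreement on "nothing" is perfect agreement, and the convention
preserves monotonicity). Volume-level scoring is the default (a
per-slice mode exists behind a flag). For every scan the reconstructed
3D masks are rendered from six axis-aligned directions (front, left,
rear, right, top, bottom) as orthographic first-hit depth-shaded
surfaces, and each view pair is compared with the spectral angle mapper
(one global angle between the flattened images — per-pixel SAM is
degenerate for a single band) and the structural similarity index with
the standard constants `k1 = 0.01, k2 = 0.03, L = 255`, computed from
global image statistics (a windowed variant is configurable). A
silhouette render mode (binary, unshaded) is also provided since the
shading convention is a free choice.

## The synthetic phantoms

No public dataset accompanies the clinical cohort, so the package ships
a generator of lower-abdomen-like CT phantoms: a soft-tissue background
(20–80 HU with a smooth spatial modulation), two mirrored femur-like
composites (cylindrical shaft + spherical head + ellipsoidal trochanter)
at cortical-bone attenuation (300–1200 HU, inside the bone window so the
phantoms are localizable), and additive Gaussian noise (sigma 15 HU)
applied before windowing. Slice spacing defaults to 3 mm. Ground-truth
masks are exact by construction.

Posture is modeled the way it matters clinically: prone scans mirror the
volume antero-posteriorly *and* left-right (a prone patient is flipped
on the couch), so the image side on which the left femur appears depends
on the posture. This makes the posture attribute genuinely informative
for left-femur segmentation rather than decorative. Per-scan pose jitter
(up to 2 voxels) and a 0.9–1.1 size factor provide cohort variation.

The head and trochanter are radially inscribed in the shaft, making the
mask near-prismatic. This is deliberate (see the localization
limitation above): protruding epiphyses are incompatible with
extent-averaged localization at any threshold. Consequently the
phantoms exercise every pipeline stage — windowing, localization,
cropping, augmentation, learning, evaluation — but they do not test
anatomical shape fidelity, partial-volume effects, CT physics (beam
hardening, metal artifacts), or pathology. Passing tests demonstrate
that the *mechanism* works, not that clinical accuracy transfers.

## Desk-scale profile

All defaults that matter scientifically live in two profiles.
`reference_profile()` keeps the clinical-scale settings (512 x 512
slices, 64-channel U-Net, 352 x 208 input, thresholds 50/5, up to 5000
epochs, patience 50). `desk_profile()` is sized for one CPU core:

* phantoms of 32 x 48 x 48 voxels, 12 scans, half prone;
* 3 axial slices per scan, sampled evenly inside the located z-extent
  (slice sampling is shared across categories so comparisons stay
  paired);
* axial crops of 32 x 32 pixels;
* a 16-channel five-level U-Net (~1.9 M parameters);
* Adam at 0.001, batch 2, at most 40 epochs, patience 8 on validation
  IoU.

These sizes were chosen once from layer-cost measurements so that a full
two-category, three-seed comparison completes in minutes; they are the
package's own desk-experiment conditions, not tuned quantities. Under
this profile the cropped-plus-attribute category (F-IV) is expected to
dominate the raw category (F-I): the crop concentrates model capacity on
the femur region, and the attribute column resolves the left/right
ambiguity that posture mirroring creates.

## Degenerate inputs and tie rules collected

* `WW < 1` is rejected; non-finite HU values are an error naming the
  offending pixel.
* A profile that never reaches its threshold yields "no extent" (a
  value, not an error); a volume in which no slice qualifies raises
  "target structure not found".
* Probability exactly 0.5 classifies as foreground.
* Empty-vs-empty masks score DSC = IoU = 1; SAM is undefined for a zero
  vector (error), and view comparisons of two empty renders are scored
  as perfect agreement.
* Max-pool ties resolve to the first element in column-major order,
  fixed so training is bit-reproducible under a seed.

## Limitations

* The localization averaging under-covers protruding structures (see
  above); the clinical remedy is the generous fixed crop size.
* Global-statistics SSIM on depth-shaded renders is sensitive to the
  shading convention; the silhouette mode trades sensitivity for
  robustness.
* The phantom cohort is geometrically simple; DSC values obtained on it
  say nothing quantitative about clinical CT.
* Training is CPU-bound R/C++ with no GPU path; the reference
  configuration (64 channels at 352 x 208) trains, but slowly, and is
  intended for completeness rather than routine use.
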