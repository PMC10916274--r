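---
title: "Multimodal histology registration with histreg: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal histology registration with histreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histreg)
```

## The problem

Histology workflows annotate one modality (usually brightfield H&E) and
need those annotations in another (e.g. non-linear optical, NLO,
microscopy of the same section). The two modalities invert each other's
intensity conventions — in NLO the tissue is bright and the background
dark, in H&E the reverse — and differ in texture statistics, which defeats
naive intensity-based alignment. `histreg` treats the problem as planar
projective registration: estimate a homography $H$ from the moving image's
frame to the fixed image's frame, warp the moving image through it, and
push annotation polygons through the same matrix.

A homography is the right model for serial-section microscopy to the
extent that the dominant misalignment is rigid or perspective-like
(placement, rotation, modest scale and shear). It cannot express elastic
tissue deformation; that limitation is inherited by everything downstream
and is discussed under *Limitations*.

## The plugin contract

Registration algorithms are plugins: single R source files defining
`plugin_name` and `plugin_entry(fixed, moving, options)`. A plugin returns
a list with exactly eight permitted keys:

| key | status | content |
|---|---|---|
| `succ` | mandatory | scalar logical success flag |
| `warping` | mandatory on success | moving image warped onto the fixed canvas |
| `Homography` | mandatory when the project has annotations | 3×3 invertible matrix, moving → fixed |
| `f_fix`, `f_mov` | optional | keypoint diagnostic images |
| `line_matching` | optional | match visualization |
| `metrics` | optional | named list of quality metrics |
| `messages` | mandatory on failure | human-readable log / error text |

`validate_result()` enforces this contract strictly: unknown keys are
rejected, a successful `warping` must have the fixed image's height and
width (a silent shape mismatch would corrupt every downstream view), and a
failed result must explain itself. The engine (`execute_pair()`) converts
plugin exceptions into failure results, so one misbehaving plugin never
aborts the remaining (pair × plugin) grid of a project run.

The direction convention matters: `Homography` is the matrix that produces
the warped moving image, and annotations are loaded *for moving images*,
so annotation vertices are transformed by $H$ directly — never by its
inverse. The synthetic-fixture generator follows the same convention,
which the ground-truth closure tests exploit.

## Annotations: masks to COCO and back

Three input formats are accepted: mask images (1- or 3-channel, 8- or
16-bit; for 3-channel images the channel order is BGR, matching the
OpenCV-style tooling such annotations typically come from), `.npz`
archives holding one `[x, y, nC]` array, and COCO JSON. Everything is
normalized to COCO instance polygons:

1. Each class plane is binarized (any nonzero value → 1).
2. Connected regions (4-connectivity) are found per plane.
3. Each region's outer contour is traced by marching squares at iso-level
   0.5 on a one-pixel zero-padded copy — the padding is what closes
   contours of regions touching the image border. With 0-based pixel
   centres at integers, contour vertices land on pixel-edge midpoints
   (a filled rectangle spanning columns 2–11 gets a bbox from 1.5 to
   11.5).
4. Collinear vertex runs are dropped; contours with fewer than 3 vertices
   or shoelace area below `min_area` (default 1 px²) are discarded with a
   reported count.

The `area` field is the shoelace area of the polygon (COCO convention),
not a pixel count; for a convex region the two differ by at most half the
perimeter, which is the tolerance used in the tests. Holes in annular
regions are ignored (outer contour only): COCO polygon segmentation has no
portable hole encoding short of RLE, which this package deliberately does
not emit. The background of a 3-channel annotation image is treated as an
ordinary class — whether to include it is the caller's choice when filling
in the class specification.

`rasterize_annotations()` is the inverse operation (even-odd fill sampled
at pixel centres). Because contours sit on edge midpoints and centres on
integers, the composition mask → COCO → mask recovers smooth regions
essentially exactly; the tests require per-instance IoU ≥ 0.99 on
elliptical fixtures and instance-count stability under a second
conversion.

## The reference plugins

No feature-detection library is available to R here, so the chain is
implemented in the package and kept deliberately classical:

* **Detection.** Harris corners (derivative scale 1 px, integration scale
  2 px, $k = 0.04$), non-maximum suppression over a 9×9 window, border
  margin 20 px, at up to 2 octaves obtained by area-averaged halving; up
  to 500 keypoints by response. Keypoint positions are refined to
  sub-pixel by a 1-D parabolic fit of the response in each axis — without
  this, the half-pixel quantization noise dominates the homography's
  corner error.
* **Orientation.** Dominant gradient orientation from a 36-bin,
  Gaussian-weighted (σ = 4.5 px) histogram over a radius-8 window,
  circularly smoothed.
* **SIFT-like descriptor.** 16×16 samples on a grid rotated into the
  keypoint frame, gradients rotated likewise, accumulated into 4×4 spatial
  cells × 8 orientation bins (128-d), Gaussian-weighted, L2-normalized
  with 0.2 clipping and renormalization. Euclidean matching.
* **ORB-like descriptor.** 256 intensity comparisons at a fixed
  Gaussian-sampled pattern (generated once from a frozen seed), rotated
  per keypoint, on a σ = 2 smoothed image. Hamming matching.
* **Matching.** Brute-force k = 2 nearest neighbours with the ratio test
  at 0.75. Exact search is used instead of an approximate index: at ≤ 500
  descriptors a side, exactness costs nothing and removes a source of
  nondeterminism.
* **Estimation.** RANSAC (2000 iterations, fixed seed exposed as option
  `seed`, default 0) over 4-point samples, degenerate (collinear) samples
  skipped, normalized DLT, inliers at 5 px reprojection, then an
  iterative refit: re-estimate on inliers, recompute the consensus set,
  repeat until stable (≤ 5 rounds). The seeded sampler makes
  `homography.json` byte-reproducible across runs; the estimator saves
  and restores the caller's RNG state.

The ratio threshold (0.75), reprojection threshold (5 px) and minimum
match count (4) are standard practice values, exposed as options rather
than tuned per dataset. A `max_dim` image cap exists as an option for
memory-constrained use and is off by default: plugins receive raw
resolution.

The modality preprocessing (`he` = invert + stretch, `nlo` = stretch,
`generic` = grayscale only) reflects the opposing intensity conventions
described above. It is parameter-free by design; choosing the right tag
per side is the caller's (or CLI flag's) responsibility.

## Metrics

`ssd` (on intensities normalized to [0, 1]), `ncc` (Pearson correlation of
flattened intensities; errors on zero-variance input rather than returning
NaN), `mutual_information` (joint histogram, 64 bins per axis, base-2 log,
empty cells skipped; `MI(a, a)` equals the histogram entropy of `a`), and
`tre` (per-landmark Euclidean error of the transformed moving landmarks).
"Relative" TRE is not defined precisely in common usage, so `tre()` emits
both the raw pixel distances and the distances normalized by the
fixed-image diagonal when the image size is supplied; consumers can pick
either reading.

The 64-bin MI default is a compromise: enough bins to resolve the
bimodal histograms of tissue/background imagery, few enough that a
512×512 image still populates the joint histogram densely.

## Pyramids and views

Every input and result image can be tiled into a multiresolution pyramid:
level $n-1$ is the unmodified source, each coarser level ceiling-halves
the previous one (5 → 3 → 2 → 1) with 2×2 area averaging until the larger
edge is 1, giving $n = \lceil \log_2 \max(w, h)\rceil + 1$ levels. Tiles
are `tile_size` squares (default 1024) written as lossless PNG, level 0 is
the coarsest (Deep Zoom convention, and a `.dzi` descriptor can be emitted
for viewer compatibility), and `read_region()` reassembles any rectangle
from exactly the intersecting tiles — byte-identically at the base level,
since the codec is lossless and the quantization is the source image's
own.

Six QC views exist; availability is a pure function of which result fields
are present: `original` always, `feature_extraction` iff `f_fix` and
`f_mov`, `line_matching` iff present, `warp` and `chessboard` iff the run
succeeded, `annotation` iff annotations and a homography exist. The
chessboard uses integer-division cell sizes with the remainder absorbed by
the last row/column, so every composite pixel is a verbatim copy from the
parity-determined source — a property the tests check pixel-for-pixel.

## Projects, batch pairing, persistence

A project is a plain directory: `project.json`, copied inputs plus one
pyramid per image, per-pair COCO annotations, and a `results/` tree with
`results/<plugin>/<pair>/{warped.png, homography.json, …, views/}`. No
database is used — paths and JSON capture everything the original
relational store would hold. Batch pairing sorts both folders
case-insensitively by file name (radix order, so it is locale-independent)
and pairs positionally; unequal counts are refused with both counts named.
A numeric-aware sort is available behind a flag. In batch mode annotation
files are matched to moving images by file stem. Export packs the results
tree into a real ZIP (written by the package with fixed timestamps, so
re-exporting unchanged results is byte-identical); the run log is excluded
from the archive because its timings are not reproducible artifacts.

## The synthetic fixture generator

`make_tissue_image()` emulates what the registration chain actually needs
from histology imagery: compact tissue regions with band-limited internal
speckle (so corner detectors fire densely and stably) on a darker, faintly
textured background, with exact per-blob masks. `make_pair()` derives the
moving image by resampling through the inverse ground-truth homography on
the same canvas (out-of-frame content clipped), then applies the modality
effect — `invert` for the NLO/H&E intensity opposition, `recolor` for an
eosin-toned RGB rendition, `none` — and Gaussian noise. Defaults are the
package's standard study conditions: 512×512, 5 blobs, rotation 10°,
translation (15, −7), scale 1, no projective term, noise σ = 5/255, all
randomness from a single seed.

What the generator does **not** emulate: elastic deformation, occlusions
and missing sections, stain variability, repetitive texture. Passing the
registration tests therefore demonstrates that the chain is correct and
accurate under rigid multimodal conditions, not that it solves the hard
deformable cases real serial sections can present — on difficult NLO↔H&E
material, feature-based rigid registration is known to fail on a fraction
of samples, which is exactly why the framework isolates algorithms behind
plugins and records failures as first-class results.

## Numerical choices and degenerate inputs

* Images are `[row, col(, channel)]` double arrays in [0, 1]; coordinates
  are 0-based with x = column, y = row; pixel centres at integers.
* Bilinear sampling treats out-of-bounds neighbours as zero-weight and
  returns a fill value (default 0) outside the image.
* `homography()` requires $|\det H| > 10^{-12}$ and normalizes the
  bottom-right element to 1 when nonzero; point mapping refuses
  projective denominators below $10^{-12}$, naming the offending point.
* Polygon edges are transformed vertex-only — exact for affine maps,
  approximate for strongly projective ones; `densify` inserts vertices
  every *d* px before mapping when that approximation matters.
  Transformed polygons are not clipped to the target canvas by default
  (lossless transfer); a flag enables clipping.
* Empty mask planes legally produce zero annotations while their category
  is kept, so category count always equals class count.
* Constant (featureless) images fail registration with an explicit
  "insufficient features" message rather than an error.

## Problem sizes used in the test-suite

The suites run on sizes chosen to exercise every code path in seconds:
192–256 px fixtures for round trips and plugin recovery, the full 512 px
default fixture once, 20 random geometries up to 4096 px for pyramid
arithmetic, and 25 seeded mask stacks for the annotation round trip.
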