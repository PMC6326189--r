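---
title: "Semi-automatic vertebral body segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic vertebral body segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertseg)
```

## The problem and the pipeline

Quantitative analysis of the lumbar spine on sagittal T2-weighted MR images
often requires delineating each vertebral body. Doing this manually for five
lumbar levels per image is tedious; fully automatic methods struggle because
trabecular bone, muscle and connective tissue share similar signal, and the
cortical rim that delimits the body is thin and locally interrupted.
`vertseg` implements a semi-automatic middle ground: the user draws **one**
rectangular region of interest (ROI) around a single vertebral body, and the
package

1. **detects** all remaining vertebral bodies by normalized cross-correlation
   template matching with iterative peak search (`detect_vertebrae()`),
2. **refines** each detected ROI — estimating the body's rotation from a
   Hough transform of its Canny edge map and counter-rotating, then extending
   the box until it contains all four body edges (`refine_roi()`),
3. **segments** each body with a hybrid scheme: minimum-cost graph paths for
   the superior/inferior boundaries and per-line rules on intensity-cluster
   ranks for the lateral boundaries (`segment_vertebra()`), and
4. **evaluates** masks with the Dice similarity coefficient, voxel counts and
   physical volumes (`dice()`, `eval_report()`).

All decisions are made on *relative* intensities: images are normalized to
[0, 1] on load, template matching is affine-invariant, edge thresholds are
gradient percentiles, and the lateral rules operate on k-means cluster ranks.
Multiplying an image by any positive constant leaves every output mask
unchanged (this is a tested invariant).

## Detection

The user crop is correlated with the patch centered at every image position
(zero-mean normalized cross-correlation, computed with FFT cross-products and
integral-image patch moments; positions where the patch exits the image are
suppressed). The global peak `p1` recovers the user's own vertebra. After
suppressing a neighborhood of one third of the ROI size around `p1` (read as
side length, not area), the **next closest body** `p2` is taken among the
strongest remaining peaks, defining the reference distance `d = |p2 - p1|`
and the inter-body step vector. Further bodies are searched inside an
`lx x ly` window centered one step beyond the last accepted body, walking
both directions along the stack; a window peak is accepted while it scores at
least `beta` (default 0.6) of `p2`'s score and the window stays inside the
image. Two details differ deliberately from a plain "second-highest peak"
scheme:

* `p2` is the *nearest* strong peak, not the global runner-up. With per-body
  size jitter or relative rotation, a more distant body can correlate better
  than the adjacent one, which would lock `d` onto a multiple of the true
  pitch and skip bodies.
* the step is the full 2-D displacement vector, not its vertical component,
  so a spine imaged at a tilt is followed along its own axis.

**Disc refinement.** Intervertebral discs are compact, bright and unique in
shape, so their correlation map localizes better horizontally than the
bodies'. A disc template (width `lx`, height `ly/2`) is cut immediately above
the user ROI and the same peak search yields disc centers. A body whose
column deviates from the column of its surrounding discs (mean of the discs
found above and below it) by more than 10% of `ly` has its column replaced.
Two robustness choices: a body is only corrected when discs on *both* sides
were found (a one-sided disc is horizontally offset by `(d/2) sin(tilt)` on
a tilted spine), and deviations are measured relative to the *median*
deviation across bodies, which absorbs the constant offset that the disc
template inherits from being cut at the user body's column. On an upright
spine the median is near zero and the rule reduces to the plain comparison.

## ROI refinement

**Rotation.** Canny edges of the (slightly enlarged, 1.3x) crop are
transformed to a Hough accumulator over angle and distance. For a
rectangle-like outline the per-angle extent of the occupied distance cells
behaves like `w|cos(t - A)| + h|sin(t - A)|`: a sharp V-cusp at the body's
own orientation `A`. The estimate is the *interior local minimum* of this
extent curve over ±45°, for two reasons found during development: (i)
counting occupied cells (rather than measuring the first-to-last occupied
span) suffers multi-bin rasterization aliasing at low-order rational angles,
so the span is used; (ii) for aspect ratios above ~1.4 the curve's smooth
decrease toward the short-axis orientation (90° away) undercuts the cusp at
the window border, so the raw window argmin is unreliable while the interior
local minimum is unique. The crop is enlarged for estimation because an
`lx x ly` crop clips a body rotated ~30°, destroying the rectangle
signature. The ROI is then counter-rotated (`derotate_roi()`); re-estimating
on the re-extracted crop returns ~0°.

**Extension.** On the axis-aligned crop, the edge map is projected onto the
two axes. A body side that lies inside the ROI projects a strong peak near
the profile end, considerably larger than the central profile value; a side
whose interior-to-border maximum stays below `alpha` (default 1.5, the
multiplier is deliberately configurable since only "considerably larger"
semantics are prescribed) times the central value is deemed cut off, and the
ROI grows outward on that side by 10% of its original size, re-testing after
each step up to +50% per side. One border pixel is excluded at each profile
end. Extension happens after de-rotation: the projection argument assumes
axis alignment. The operation is idempotent, which the tests check.

## Segmentation

From the refined crop's edge projections, the four argmax positions on the
outer half-intervals give approximate vertex coordinates `bL, bR, bU, bD`
(ties resolved toward the ROI border). Around the vertex rectangle an
annular band of half-width `s = max(3, ceil(0.08 min(lx, ly)))` is laid out:
four rectangular bands (`U`, `D`, `L`, `R`) and four `2s x 2s` corner
squares, each split along its outer-to-inner diagonal into two triangles
(suffix 1 processed like `U`/`D`, suffix 2 like `L`/`R`). The bands tile the
annulus disjointly — an exhaustively tested property.

**Superior/inferior (graph).** The boundary through `U` (and `D`) is the
minimum-cost monotone path across the band: one pixel per column,
8-connected steps, step cost equal to the traversed pixel's intensity — the
dark cortical rim attracts the path. The dynamic program is the s/t minimum
cut of the chain graph whose nodes are the inter-pixel intervals along the
horizontal axis with pixel intensities as edge weights, computed
deterministically (ties toward the smallest row). An exhaustive
path-enumeration oracle on small bands verifies optimality. Raw intensities
are used for these bands; clustering is introduced only for the lateral
rules below.

**Lateral (line rules).** The crop is k-means clustered into `k = 10`
intensity levels (1-D clustering initialized deterministically at intensity
quantiles — with a scalar feature, random restarts add nondeterminism
without benefit; when a crop has fewer distinct intensities than `k`, `k` is
reduced). Each band line is then a vector of ranks in 1..k, scanned from the
base point `B` — the line end on the vertebra side, or the nearest intensity
peak to it — toward the background, with reference value `R = ceil(Y(B)/2)`:

* **Case 1** — a "deep" valley (at least 2 cluster stages below the peak
  beyond it, the same margin the peak-qualification rule uses) below `R`
  followed by a peak above `R`: the boundary is the deepest point between
  that peak and the base-side line end (ties toward the vertebra).
* **Case 2** — valleys exist but no qualifying peak exceeds `R`, and
  **Case 3** — no valley at all: the boundary is the point nearest `B`
  (searching toward the background) whose rank equals `ceil(Y(B)/3)`; if no
  point attains that rank the far line end is used and flagged.

The three predicates are total and mutually exclusive; the package verifies
this *exhaustively* for every rank profile of length up to 8 (about 1.1e8
profiles, via the compiled rule core).

**Corners.** Each triangle is padded to a parallelogram by replicating the
terminal pixel of every short line (empty lines copy their nearest neighbor
line); the band method of the adjoining side then runs on the padded
rectangle, and boundary points landing in padded cells are projected back
onto the triangle's hypotenuse. This is one consistent reading of the
"copying points" construction; its behavior is bounded by the later
smoothing step.

**Smoothing and fill.** Per side, a cubic polynomial is least-squares
fitted (row as a function of column for the horizontal sides, transposed for
the vertical ones); points deviating by more than `delta = 3` px (exposed as
configuration — only "a regular distance" semantics are prescribed) are
replaced by the curve value. Sides with fewer than four points stay raw. The
four sides join into a closed polygon, which is rasterized by even-odd
scanline filling in full-image coordinates.

## The synthetic phantom

No MR data ships with the package, so every stage is exercised on a
generated sagittal lumbar phantom with exact ground truth
(`generate_phantom()`). It emulates what the algorithm assumes of the data:
vertically stacked bright vertebral bodies (rounded rectangles) delineated
by a thin dark cortical rim, separated by brighter elliptical discs on a
mid-gray background, with additive Gaussian noise and an optional smooth
multiplicative bias field. Defaults follow the target acquisition geometry
at 0.39 mm pixel spacing: bodies of 80 x 52 px (~31 x 20 mm) at a 110 px
(~43 mm) center-to-center pitch, a 2 px (~0.8 mm) cortical rim, 4% per-body
size jitter, and noise at 2% of the dynamic range. The T2-like contrast
ordering is disc > body > background > rim; the ordering is configurable
because the pipeline is contrast-relative. Discs are also placed above the
first and below the last body, as in the anatomy.

What the phantom does *not* emulate: trabecular texture, partial-volume
fading of the rim near the endplates, neighboring anatomy (spinal canal,
processes, vessels), pathology, and through-plane effects. Passing the
phantom suite therefore demonstrates the pipeline's geometric and numerical
correctness under its own assumptions, not clinical-grade performance on
real MR images.

Rotation experiments follow two regimes: per-body rotations (kyphosis-like
relative tilts, with whole-stack angles up to ±30° plus ±5° per-body
jitter), and whole-image rotation of an already generated phantom
(`rotate_dataset()`, bilinear for the image, nearest-neighbor for masks).
Independent per-body draws over ±30° are *not* used: they would imply up to
60° of relative rotation between adjacent vertebrae, which no spine
exhibits, and would defeat template matching by construction rather than
measure robustness.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), rows increasing downward; angles are degrees,
  positive counter-clockwise on screen. Rasterization rounds half away from
  zero. ROIs are stored unrotated plus an angle; extraction resamples
  bilinearly.
* Correlation scores are clamped to [-1, 1]; near-constant patches
  (variance below 1e-12 per pixel) get score 0 and are suppressed. A
  constant template is an error; a constant crop yields an empty edge map,
  not an error.
* Argmax ties in peak queries break toward the smallest row, then column;
  Hough ties toward the smallest angle magnitude; path-cost ties toward the
  smallest row; Case-1 argmin ties toward the vertebra.
* Detection declares "single vertebra" when no second peak reaches 0.6, and
  "degenerate reference distance" when `d < max(lx, ly)/2`.
* If the located vertex rectangle touches the crop border (so the annulus
  cannot be placed), segmentation retries once on a 20%-enlarged crop.
* k-means clustering is deterministic by construction (quantile
  initialization, ascending-center ranks), so byte-identical reruns need no
  seed management in the segmentation path; the seed in `pipeline_config()`
  documents the run and drives phantom generation in simulation studies.

## Problem sizes used by the tests and the acceptance script

The bundled checks run on deliberately desk-sized problems: correlation
oracles on ≤128 x 128 images against a per-pixel brute-force reference;
detection and end-to-end sweeps over 20 phantoms of 3–6 bodies each;
graph-path optimality against exhaustive enumeration on bands up to 5 x 8
(100 random bands); the line-rule totality sweep over all rank profiles up
to length 8; and rotated-variant comparisons at 10/20/30°. These sizes were
chosen so the whole suite completes in a few minutes on one core while still
exercising every code path at full fidelity.

## Known limitations

* The lateral line rules are the weakest link (visible as slightly rougher
  left/right boundaries); on degenerate quantizations (noise-free synthetic
  images collapsing to very few clusters) the Case-2/3 target rank can fall
  just outside the rim.
* Detection assumes an approximately rigid stack: it tolerates global tilt
  and moderate relative rotation, but not scoliotic lateral curvature within
  the slice beyond what the disc correction absorbs.
* The `lx/2`-portion reading of the disc template ("half the ROI height
  just above the body") is one resolution of an ambiguous prescription; the
  height fraction is exposed as `disc_height_frac`.
* Single-slice only: volumes are per-slice voxel counts times
  `spacing^2 * thickness`; no 3-D extension, no DICOM series stitching.
* The minimal DICOM reader handles single-frame uncompressed little-endian
  files only (it exists because no full DICOM package is declared by this
  package; PNG/TIFF/NIfTI go through the standard readers).
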