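---
title: "Semi-automatic orbital volumetry: model, parameters and validation design"
author: "orbvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic orbital volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbvol)
```

## The measurement problem

The bony orbit is an open, roughly conical cavity. Measuring its volume on
CT is clinically important — an increase of about 1 cc of orbital volume is
associated with about 1 mm of enophthalmos — but hard for two reasons. The
medial wall and floor are thinner than a voxel, so partial volume blurs them
into intensities indistinguishable from soft tissue, and the cavity has no
intrinsic anterior boundary: the front of the orbit is open to the face and
some convention must close it before a volume can be defined.

`orbvol` implements a semi-automatic (SA) measurement convention:

1. **Initial segmentation.** A seeded region growing produces an
   over-inclusive first mask of the cavity (the role played by an
   atlas-based automatic step in clinical planning software).
2. **Bone/air refinement.** A bone mask (voxels at **+400 HU or more**) and
   an air mask (**−600 HU or less**) are formed by inclusive thresholding
   and subtracted from the initial mask; the largest connected component is
   kept. This removes the bone fragments and sinus air the first pass
   typically swallows.
3. **Anterior clipping.** Rim landmarks, placed roughly 0.5–1 cm apart
   around the orbital rim, are triangulated into a *fan surface*: each
   consecutive landmark pair is joined to the landmarks' centre of gravity.
   Every voxel whose centre lies anterior to this surface is removed.
4. **Volume.** The voxel count of the final largest component times the
   voxel volume, reported in cc (defined exactly as cm³).

The validation battery mirrors how such methods are judged against a gold
standard: volume differences in cc, the Dice coefficient, signed
surface-distance maps (mean signed distance and the 95th percentile of
absolute distances), a two-way random-effects absolute-agreement
single-measure ICC with its 95% F-based confidence interval, and a paired
two-sided t test.

## Geometry conventions

All world coordinates are the DICOM patient frame (LPS, mm); NIfTI RAS
affines are converted on read and restored on write. Voxel membership is
decided at voxel centres everywhere — thresholding, clipping, and volume all
use the same rule, so clipping is idempotent and consistent with
voxel-count volumes. Partial-voxel weighting was deliberately rejected: at
0.5 mm voxels it suggests precision the segmentation does not have.

The fan surface is the minimal surface consistent with "connect all
landmarks and their centre of gravity": triangles `(centroid, p_i, p_i+1)`
with per-triangle winding oriented along an anterior hint (default −y in
LPS). Clipping against a non-planar fan assigns each voxel to the radial
sector (about the centroid, in the ring's best-fit plane) containing its
projection and tests the signed side of that sector's supporting plane;
voxels outside all sectors use the nearest sector. For a planar ring this
reduces exactly to a half-space test, which is one of the unit-test
invariants. Rings whose projection self-crosses are rejected at validation
rather than reordered; sector assignment for non-star-shaped (but still
simple) rings falls back to the nearest sector mid-angle.

## The initial segmentation stand-in

The atlas step of clinical software is proprietary and trained on labelled
images; it is not reproduced here. What the pipeline needs from it is its
*role*: a connected, over-inclusive initial mask whose known failure modes
(sinus air, bone fragments, fissure overflow) are exactly what the
refinement corrects. The stand-in:

- builds a **barrier shell** by thresholding at `shell_threshold_hu`
  (default **+200 HU**) and morphologically closing it with a physical ball
  (`closing_radius_mm`, default 2 mm, defined in millimetres so behaviour
  is identical on anisotropic grids);
- grows a seeded region through non-shell space, bounded anteriorly by the
  fan surface, posteriorly by `posterior_extent_mm` (default 55 mm) behind
  it, and radially by the largest ring radius plus `radial_margin_mm`
  (default 2 mm) — a crude shape prior standing in for the atlas prior;
- dilates the grown core by `dilate_mm` (default 1 mm), deliberately
  re-admitting the partial-volume bone rind so the mask is a superset of
  the cavity.

Two of these defaults deserve justification. The barrier threshold is
*lower* than the refinement's bone threshold because a 0.5 mm wall imaged
at 0.5 mm voxels genuinely drops below +400 HU through partial volume
(its blurred peak is roughly `wall_HU × (2Φ(t/2σ) − 1)`); a barrier at
+400 threads those pinholes and floods the face, while +200 stays below
the thinnest blurred wall the package's difficulty range produces yet far
above soft tissue (~30 HU). The refinement then applies the strict
+400/−600 masks, so the *final* boundary is always set by the published
thresholds, not by the barrier. The dilation is 1 mm because the +200
barrier leaves the core roughly half a millimetre inside the cavity (at
the 200-crossing of the blurred edge); 1 mm reliably carries the mask past
the +400 crossing, and the refinement trims it back. A larger dilation
(1.5 mm) was rejected: it pushes through sub-voxel walls and leaves rind
outside the orbit that the bone mask cannot remove.

Errors are classified: a seed inside the closed shell is a seed error; a
seed outside the orbital search region, or a grown region exceeding three
times the prism of the fan-surface area times the posterior extent, is a
leak error naming the likely wall gap.

## The synthetic orbit phantom

Because no clinical scans ship with the package, all end-to-end claims are
made on a deterministic phantom with a closed-form ground truth:

- **Cavity**: a half-ellipsoid with semi-axes (a, b, c) = (17.5, 17.5, 45)
  mm opening anteriorly; analytic volume (2/3)·π·a·b·c = **28.86 cc**, the
  scale of an adult orbit. The ground-truth label is the *pre-blur* cavity:
  blur models acquisition, not anatomy.
- **Wall**: an analytic shell between the cavity ellipsoid and the
  ellipsoid grown by `wall_thickness_mm` (default 1 mm) at +1000 HU. The
  bony rim continues 2 mm anterior of the rim plane around the rim
  annulus — a knife-edge wall ending exactly at the plane would blur below
  the bone threshold at its free edge, which real rims (which continue into
  the facial skeleton) do not do.
- **Sinus**: an air block (−1000 HU) hugging the medial wall, separated
  from the wall's outer surface by a 1 mm soft-tissue standoff. The
  standoff plays the role of mucosa-lined bone: air immediately behind a
  thin wall hollows out the wall's +400 band and perforates it, which is
  not how an intact lamina behaves.
- **Fissure**: a corridor of `fissure_width_mm` (default 2 mm) from the
  cavity through the infero-medial wall toward the sinus, running through a
  locally thickened bone collar — a slot through thick bone, as at the real
  inferior orbital fissure. The geometry is chosen so the default corridor
  is a tube the 2 mm closing ball seals, while a doubled corridor stays
  open at the bone threshold; the fissure is the clinically dominant
  error source and the package reproduces its direction: widening the
  fissure strictly increases the initial-stage volume error.
- **Acquisition model**: `blur_sigma_mm` (default 0.5 mm) is the *total*
  Gaussian-equivalent partial-volume width. Rendering first averages
  interface voxels exactly (3×3×3 supersampling of the analytic anatomy;
  a binary rendering would punch spurious holes through sub-voxel walls),
  which contributes spacing²/12 of variance, and then applies a Gaussian
  PSF with the remaining variance. With `blur_sigma_mm = 0` the sharp
  rendering is kept, so the noiseless, unblurred phantom contains exactly
  the four tissue intensities. Additive Gaussian noise (`noise_sd_hu`,
  default 10) is seeded from the spec; the truth label and landmarks carry
  no randomness.
- **Landmarks**: sampled every ~8 mm on the exact rim ellipse, so
  anterior-plane tests have an analytic reference.

`phantomSweep()` freezes the difficulty battery: ten phantoms whose wall
thickness spans 0.5–1.5 mm (evenly) crossed with blur 0.3–0.7 mm
(cycling), a design-of-experiments grid over the two parameters that govern
thin-wall visibility.

### What the phantom does and does not show

The phantom reproduces the *mechanisms* that make orbital volumetry hard —
sub-voxel walls, adjacent pneumatised spaces, a wall-breaching fissure,
partial volume, noise, and the open anterior boundary — with a known
volume. It does not reproduce anatomical shape detail (no true fissure
anatomy, optic canal, or fracture defects), scanner reconstruction kernels,
metal artefacts, or inter-patient shape variability. Green tests therefore
demonstrate correctness of the algorithms and the direction and scale of
their error mechanisms, not clinical accuracy on real heads.

### Known accuracy limits

On the default phantom the pipeline underestimates the analytic volume by
about 1.97% (≈0.57 cc). This is the one-sided partial-volume bias of the
+400 HU convention itself: the blurred cavity–wall edge crosses +400 about
`σ·Φ⁻¹(0.38) ≈ 0.14 mm` on the cavity side of the true interface, and the
cavity surface is ≈4100 mm². The bias is a property of the published
thresholds on this geometry, not of the implementation; against a *manual*
gold standard (which traces the same blurred boundary) it largely cancels,
which is consistent with the much smaller mean differences reported for
such methods clinically. Across the difficulty sweep the mean absolute
error is ≈0.4 cc, within the ~1 cc-per-mm-enophthalmos clinical scale.

## Rater simulation and agreement statistics

`simulateRaters()` emulates observers who consistently over- or
under-trace the boundary: each rater/subject draws a uniform offset in
±`boundary_jitter_mm` and the analytic cavity is inflated by that offset
and re-voxelised. Offsets scale linearly with the jitter under a fixed
seed, so agreement degrades monotonically — a property the tests assert.
The ICC cohort spans cavity scale factors 0.85–1.15 (volumes ≈18–44 cc);
at 0.25 mm jitter this reproduces the >0.99 interobserver ICC regime of
landmark-based anterior boundaries. With a subject spread as narrow as a
homogeneous clinical series (SD ≈ 2.3 cc) the same jitter yields ICC ≈
0.94 — absolute-agreement ICCs are cohort-dependent, which is why the
model label is printed in every report.

The ICC is McGraw–Wong ICC(A,1): two-way random effects, absolute
agreement, single measure, computed from the two-way ANOVA mean squares
(`stats::aov`) with the standard F-based 95% interval; the unit tests pin
it to an explicit sums-of-squares oracle at 1e-10. Distances are
one-directional (test boundary → reference surface), signed by containment
in the reference, with a symmetric option; the 95th percentile uses linear
interpolation between order statistics (quantile type 7). Both the mean
*signed* and mean *absolute* distances are reported, since either may be
meant by a "mean distance measure". Empty-vs-empty Dice is defined as 1.

## Numerical choices

- Thresholds are inclusive (`≥ lo`, `≤ hi`), matching "or more"/"or less".
- Connectivity defaults to 26; component ties break deterministically
  toward the component containing the smallest column-major voxel index.
- Morphological elements are Euclidean balls in millimetres implemented by
  an exact anisotropic distance transform; closing is therefore exactly
  idempotent and extensive.
- Surface distances use the same exact distance transform; magnitudes
  equal the all-pairs nearest-neighbour oracle to machine precision.
- The pipeline contains no randomness: identical inputs give bit-identical
  masks, volumes and output files. Phantom noise is drawn under a local
  RNG seeded from the spec, leaving global RNG state untouched.
- Degenerate inputs are classed errors: empty masks in distance maps,
  zero-variance paired differences, constant rating tables, seeds inside
  bone, self-crossing rings; collinear fan triangles only warn and are
  kept with zero area.

## Problem sizes used in the shipped tests

The test-suite pipeline runs use the default phantom grid
(102×116×86 voxels at 0.5 mm) for end-to-end claims and a reduced
12×12×30 mm cavity for smoke tests; oracle equivalence uses ≥200 random
mask pairs up to 16³ and 100+ random rating tables; the voxelisation
convergence study uses 1.0, 0.5 and 0.25 mm grids. These sizes were chosen
so that the complete suite characterises every mechanism in a few minutes
on a single core.

## A worked example

```{r example, eval = FALSE}
library(orbvol)

case <- generatePhantom(phantomSpec(seed = 1))
res <- measureOrbitalVolume(case@volume, case@landmarks)
res
#> OrbitalVolumeResult
#>   auto      31.41 cc
#>   sa        29.22 cc
#>   clipped   28.29 cc
#>   final     28.29 cc
#>   orbital volume: 28.29 cc

compareMasks(res@clipped_mask, case@truth_mask)
#> AgreementReport
#>   volumes: test 28.29 cc, ref 28.87 cc, diff -0.58 cc
#>   dice 0.9899; mean signed distance -0.126 mm, p95 |d| 0.500 mm
```

The 0.58 cc deficit is the partial-volume bias discussed above; the Dice
and distance summaries sit in the regime reported for semi-automatic
orbital segmentation against manual gold standards.
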