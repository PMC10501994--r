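---
title: "Geometric methods behind the AAA screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric methods behind the AAA screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aortascreen)
```

## The measurement problem

Abdominal aortic aneurysm (AAA) screening reduces to one number per patient:
the maximum wall-to-wall diameter of the infrarenal aorta, measured
perpendicular to the vessel centerline, compared against a 30 mm threshold.
"Wall to wall" means the outer wall: when an intraluminal thrombus lines the
aneurysm sac, the diameter is taken across the thrombus, not just the
contrast-filled lumen. This package implements the geometric pipeline that
turns a pair of segmentation masks (lumen, thrombus) into that number,
assuming the segmentation itself is produced upstream (e.g. by a CNN).

The pipeline is deterministic: identical masks produce bit-identical
measurements. The only randomness in the package lives in the phantom
generator.

## Pipeline stages and their assumptions

**Canonical orientation.** All "highest z" rules assume z increases toward
the superior direction. NIfTI files whose header declares an
inferior-increasing third axis are flipped on read; masks are assumed
axis-aligned. Voxel indices are 1-based in R; physical coordinates are mm.

**Mask fusion and smoothing.** The whole-aorta mask is the binary union of
lumen and thrombus. Smoothing is morphological closing followed by opening
with a Euclidean ball (default radius 1.5 mm), realised exactly by
thresholding the squared Euclidean distance transform (EDT) rather than by an
approximate discrete structuring element. Closing fills surface pits and
cracks between lumen and thrombus; opening removes spikes and isolated
islands. The order (closing before opening) removes both kinds of defects
symmetrically; the radius and order are configuration-exposed because the
appropriate scale depends on segmentation noise.

**Surface extraction.** The isosurface at level 0.5 is triangulated by a
marching-tetrahedra variant of marching cubes on the Kuhn 6-tetrahedron cube
split, which is translation-invariant and therefore watertight by
construction. The binary indicator is first smoothed with a small Gaussian
(sigma 1 voxel): a binary field produces a staircase surface whose area
overestimates curved anatomy, while the 0.5 level set of the smoothed
indicator is unmoved for locally flat boundaries and shifts curved boundaries
by only ~sigma^2/r. On a digital sphere of radius 10 mm at 0.5 mm voxels the
mesh area is within 0.1% and the enclosed volume within 1% of the closed
forms (the test suite asserts 5% and 3%). Meshes are produced on the native,
possibly anisotropic grid; no resampling of labels occurs before surfacing.

**Axial bounding.** Slice-wise 8-connected component counts locate two
transitions where the count drops from >= 2 (below) to 1: the aortic arch
apex (ascending + descending limbs merging) and the iliac bifurcation apex.
The two cases are distinguished by what lies above the transition: at the
arch the foreground ends within roughly a tube radius (25 mm budget), at the
iliac apex the trunk continues far upward. The crop keeps a 15 mm margin
below the iliac transition so the proximal common-iliac stubs survive (the
branch decomposition later needs the bifurcation inside the model) and cuts
3 mm below the arch transition so the ascending and descending limbs
separate; the largest connected component — the descending/abdominal tract —
is retained. With no usable transition (a straight tube) the full extent is
used and flagged degenerate.

**Skeletonization.** The raw center lumen line is obtained by
distance-ordered homotopic thinning of the lumen mask after isotropic
nearest-neighbour resampling (3D thinning assumes isotropic adjacency):
border voxels are deleted in increasing EDT order whenever deletion preserves
topology (simple-point test: one 26-connected foreground component in the
neighbourhood, one 6-connected background component among the face
neighbours), keeping chain endpoints (< 2 foreground 26-neighbours). Limbs
shorter than 5 mm are pruned before endpoint extraction — thinning noise
around branch junctions otherwise creates spurious seeds. The endpoint with
the highest z is the source seed; the rest are targets.

**Refined centerline.** The center aortic line is computed on the fused
aorta mask as a shortest path over the foreground voxel graph
(26-neighbourhood) with edge cost `length / (clearance + eps)^2`, where
clearance is the EDT in mm — paths maximise their distance from the wall,
i.e. follow the medial axis. Each raw path is smoothed with a cubic smoothing
spline per coordinate against arc length (smooth factor 0.5 maps linearly to
`smooth.spline`'s `spar` via `0.3 + 0.7 * f`; factor 0 disables smoothing)
and resampled every 2.5 mm. The maximal inscribed-sphere radius (interpolated
EDT) is recorded per point. On phantoms the recovered line stays within
0.25 mm of the analytic axis of a quarter-torus tube and within a voxel of a
straight cylinder's axis, with arc length within 2% of the closed form.

**Branch decomposition and the renal plane.** Paths from one source form a
shortest-path tree, so the centerline splits exactly where tree paths to
different targets diverge. The tree fork can be displaced from the anatomical
take-off in two ways: paths may run side by side inside the shared trunk
after forking topologically, and inside a wide aneurysmal chamber they may
fork early and re-converge below it. The plane origin is therefore refined to
the last point at which all child paths still lie within 2.5 mm of each
other. The most inferior divergence is the iliac bifurcation; the lowest
remaining one is taken as the renal take-off ("the last bifurcation above the
iliacs is renal"). This rule would mislabel a celiac or superior mesenteric
take-off if the renal arteries were missing from the segmentation — a known
failure mode; the plane choice is overridable. On phantoms both planes land
within ~2 mm of the analytic branch levels (5 mm asserted).

**Abdominal clipping and sectioning.** The surface is clipped by the renal
plane (normal facing inferior) and the iliac plane (normal facing superior),
both perpendicular to the centerline, with cut rings capped; the abdominal
centerline is recomputed between the two plane origins inside the slab
between the planes. Sections are cut every 2.5 mm (default: the centerline
resampling step; the spacing of the "equidistant" sections is otherwise
unspecified, so it is configuration-exposed). Sectioning starts 8 mm below
the renal plane and stops 2.5 mm above the iliac plane: within those bands a
perpendicular plane grazes the renal ostia or the bifurcation saddle and the
contour would include branch-mouth tissue, biasing the diameter upward by
several millimetres on small aortas. Of each plane's intersection loops only
the closed loop containing the centerline point is kept; open chains (cut
boundaries) and grazing loops through other limbs are discarded with a
warning.

**Diameter definition.** The per-section wall-to-wall diameter is the
maximum Feret diameter of the contour — the largest pairwise distance between
contour points, computed on the convex hull — matching the clinical wall-to-
wall definition used for the manual reference measurements. The
equivalent-circle diameter `2*sqrt(area/pi)` is emitted alongside for
comparison but plays no role in classification. The case diameter is the
maximum over sections, ties broken toward the more superior section.

**Thrombus volume.** Foreground voxel count times voxel volume, reported in
mL; an empty mask gives 0 (aneurysms without thrombus are legitimate). No
partial-volume correction is attempted.

**Classification and metrics.** AAA iff diameter strictly greater than
30 mm: equality is a control, following the "greater than the threshold"
phrasing of the clinical rule. Rates are reported as percentages rounded to
integers by default (raw values are also emitted); a zero denominator yields
NA rather than 0. Percentiles use linear interpolation between order
statistics (R quantile type 7) and SD is the sample (n-1) form.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `threshold_mm` | 30 | mm | AAA classification threshold (strict >) |
| `resampling_step_mm` | 2.5 | mm | centerline resampling / section spacing |
| `smooth_factor` | 0.5 | – | centerline spline smoothing in [0, 1] |
| `smoothing_radius_mm` | 1.5 | mm | morphological ball radius |
| `prune_length_mm` | 5 | mm | skeleton spur suppression |
| `binarize_threshold` | 0.5 | – | probability-map binarization (strict >) |
| `arch_margin_mm` | 3 | mm | crop margin below the arch transition |
| `iliac_margin_mm` | 15 | mm | iliac stubs kept below the iliac transition |
| `renal_inset_mm` | 8 | mm | sectioning inset below the renal plane |
| `iliac_inset_mm` | 2.5 | mm | sectioning inset above the iliac plane |
| `surface_sigma_vox` | 1 | voxel | Gaussian pre-smoothing for isosurfacing |

The multi-view fusion utility averages axial, sagittal and coronal
probability maps voxelwise; the binarization threshold of 0.5 with a strict
inequality is a symmetric default. The Dice coefficient is
`2|A∩B| / (|A|+|B|)`; its prose description as "divided by the union" is
ambiguous, and the standard size-sum form is implemented, with the
both-empty case defined as 1 (perfect agreement on absence).

## The phantom generator

Real masks cannot ship with the package, so every stage is validated on
synthetic aortas with analytic ground truth: a gently bowed trunk (optionally
continuing over a candy-cane thoracic arch with an ascending stub), a renal
pair leaving nearly laterally and slightly upward, an iliac split as the most
inferior divergence, a Gaussian fusiform bulge, and a thrombus annulus whose
thickness follows the bulge (contributing ~40% of the dilation, leaving the
rest to lumen dilation). Voxelization assigns each voxel to its nearest
centre-curve point (verified exactly against a windowed search — bounded
stamping alone lets distant fat samples claim voxels their thin nearest
sample does not reach); a smooth radial jitter (spline through Gaussian knots
every 10 mm, amplitude 0.3 mm) emulates segmentation surface noise.
Default spacing is 0.75 mm isotropic, a typical CTA slice thickness.

Ground truth records the maximum outer diameter over the infrarenal tract
(the clinical measurement territory) with its location, the thrombus volume
as a 0.01 mm-step numerical integral of the annulus, branch z levels, the
analytic centerline at 0.5 mm, and the true class. A bulge overlapping a
branch take-off is rejected at construction so the truth stays unambiguous.

What the phantoms do **not** emulate: non-circular (saccular or dissected)
lumina, calcification, touching or kissing vessels, accessory renal
arteries, segmentation dropouts, and anisotropic voxels with large slice
thickness. Passing the phantom suites therefore demonstrates geometric
correctness of the pipeline, not robustness to segmentation pathology.

Cohort generation draws AAA outer diameters uniformly from [32, 90] mm (with
thrombus) and controls from [16, 28] mm (without), bracketing reported
screening cohorts; ranges are arguments, and the screening-correctness suite
uses [33, 90] / [16, 27] so every case is at least 3 mm clear of the
threshold, isolating pipeline errors from genuine borderline ambiguity (the
documented misclassification mode of threshold screening).

## Problem sizes and runtime

The test and acceptance workloads are sized for a single CPU: the diameter
sweep uses 20 phantoms spanning 18–90 mm at 0.75 mm voxels (volumes up to
~150^2 x 250 voxels, ~15 s per case end to end), the screening cohort 10 AAA
+ 10 controls, and the oracle fixtures (cylinder, quarter torus, inverted-U,
Y-tube, spheres) a few seconds each. The full acceptance script completes in
roughly ten minutes.

## Known limitations

- The renal-plane rule assumes the renal arteries are the lowest non-iliac
  branches present in the segmentation; visceral vessels above them are fine,
  missing renals are not.
- Diameter accuracy is voxel-limited: errors scale with spacing (sub-voxel
  on the phantoms at 0.75 mm) and the morphological smoothing radius trades
  segmentation-noise robustness against erosion of sharp thrombus margins.
- Sections are planar; in a strongly kinked aneurysm neck a perpendicular
  plane can cut the sac obliquely. The containing-loop rule prevents limb
  contamination but cannot repair a genuinely oblique cut.
- MetaImage support covers uncompressed scalar volumes only.
- Thoracic measurement (45 mm threshold) is out of scope; the pipeline
  deliberately discards everything above the renal plane.
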