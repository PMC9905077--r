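---
title: "Methods: synthetic cochlear CECT morphometry and trauma quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cochlear CECT morphometry and trauma quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind cochleaCT: what the synthetic cochlea emulates, how each measurement
is defined, and where the design was genuinely open and a convention had to
be fixed.

## Why a synthetic cochlea

Contrast-enhanced microCT (CECT) studies of cadaveric cochleae measure
quantities — turn counts, unwrapped angular positions, structure volumes,
centerline lengths, membrane thickness profiles, electrode insertion depth
and trauma fractions — on manually segmented volumes that are rarely
publicly deposited. None of the measurement algorithms, however, depend on
the provenance of the segmentation. cochleaCT therefore couples the
measurement chain to a phantom generator whose geometry is continuous and
known exactly, so every stage can be validated as a parameter-recovery
problem: generate at a known value, measure, compare. Passing these tests
demonstrates that the algorithms are correct and internally consistent at
the stated tolerances; it does not demonstrate robustness to the
segmentation noise, anatomical variability or staining inhomogeneity of
real specimens.

## The phantom model

### Spiral geometry

The cochlear duct is a tube swept along an elliptical spiral parameterized
directly by azimuth: at unwrapped angle $\psi$ (degrees, 0 at the round
window, increasing base to apex), the centerline sits at radius

$$ r_c(\psi) = e^{-\lambda \psi} \,
   \frac{a_0 b_0}{\sqrt{(b_0\cos\psi)^2 + (a_0\sin\psi)^2}}, \qquad
   z_c(\psi) = \frac{p\,\psi}{360}, $$

with $\lambda = -\ln(1 - d)/2\pi$ for a radius decay fraction $d$ per turn
(default 0.45) and axial pitch $p$. A purely circular decaying spiral
cannot simultaneously reach realistic cochlear length-to-width ratios
(solving for both forces the radius negative before 2.8 turns), and a
linear decay has the same problem; the elliptical spiral with exponential
decay matches any feasible length/width pair while keeping every angular
ground truth exact, because the parameter *is* the azimuth. The semi-axes
$a_0, b_0$ and pitch are solved from the requested bounding length, width
and height analytically and then refined in four fixed-point iterations
against the exact numeric envelope, so generated phantoms hit their target
dimensions to well below a voxel.

The duct radius decays with the same per-turn factor (basal default
0.85 mm). Adjacent turns are kept separate by a Voronoi-style wall rule:
a voxel belongs to the lumen of its nearest turn only if its margin to the
second-nearest turn exceeds `wall_min_um` (default 120 µm); the contested
shell is bone. A short basal vestibule ($\psi \in [-18°, 0)$) behind the
round window keeps the basal duct radius and carries the round window
membrane as a shell patch, with the round window arch as a dense arc along
its upper rim and an air-filled niche outside the membrane.

### Cross-section anatomy

Within the duct disc of local radius $R$, structures are defined in local
(radial, axial) offsets $(a, b)$: the osseous spiral lamina occupies the
partition slab from the inner wall to $-0.1R$; the basilar membrane
continues it to $0.38R$; the cochlear partition bridge/organ of Corti block
sits on the membrane; the Reissner membrane slab at height $0.38R$ closes
the scala media pocket; the secondary spiral lamina is an outer-wall ridge
(porous bone) present over its angular range (default ending at 572°); the
spiral ligament lines the outer wall, capped at 35% of the local duct
radius (floored at 1.5 voxels so the apical tail rasterizes contiguously).
Fluid below the partition is scala tympani, the pocket is scala media, the
remainder scala vestibuli. Rosenthal's canal is a tube offset inward from
the duct (default spanning 0–990°, i.e. into the third turn), sheathed in
bone; the modiolus is a central bone cylinder; the capsule is a bone shell
around each turn. Two reference blocks (cortical-bone and parafilm
analogs) sit near the grid edge.

All membrane thicknesses are absolute (µm) and validated against the voxel
size: any structure thinner than one voxel aborts generation naming the
structure. Consequently desk-scale phantoms use thickened membranes (BM
default 90 µm); the true-scale 25 µm membrane case is exercised in the
high-resolution cropped membrane-patch mode (6.3 µm voxels,
`generate_membrane_patch()`), and the trauma report's volume-reliability
flag — ground-truth thickness below two segmentation voxels — covers the
thin-membrane bookkeeping at any resolution.

### Ground truth

The same continuous classifier that rasterizes the cross-section is
integrated on a fine quadrature grid (480 angular × 72² in-plane points,
cylindrical volume element $(r_c + a)\,da\,db\,d\phi$) to produce the
ground-truth table: per-structure volumes, duct and scala-tympani
centerline lengths (arc length of the quadrature centroid track), bounding
dimensions from the exact envelope, membrane thicknesses and angular
ranges. The truth is therefore independent of the raster; raster-vs-truth
agreement (within 5% for volumes at the test resolution) is itself a test.

### Staining and electrode

Contrast uptake follows a logistic angular front,
$u(\psi, t) = \max\{0,\ 2[\sigma((F(t) - \psi)/w) - \tfrac12]\}$ with
$F(t) = 360\,\rho\,t/24$ for a rate $\rho$ in turns/day (default 1) and
front width $w = 30°$; uptake is 0 everywhere at $t = 0$, monotone in time,
non-increasing in angular distance, and the round window membrane is
treated as fully stained from 3 h (it faces the bath directly). "Stained"
means uptake above 0.5 — the front has passed. Under the defaults a
2.8-turn phantom is fully stained on day 3 and not on day 2.

The electrode is a tube along the scala tympani at offset $-0.55R$,
tapering to at most 33% of the local duct radius, clipped at the requested
angular depth (a flat tip, so the most apical voxels sit at the requested
depth), and it only ever replaces open scala tympani fluid — an electrode
in an open scala is not trauma. Lesions remove (fracture/tear) or displace
(elevation/deformation, shifted apex-ward into the first open fluid) voxels
of a named structure over an angular range, with exact bookkeeping of the
removed voxel set; a scala-vestibuli translocation reroutes the electrode
segment upward. Each lesion maps to an Eshraghi descriptor where the scale
defines one.

## Measurement conventions

* **Frame fitting.** The modiolar axis is the first principal component of
  the modiolus label (falling back to the minimum-variance direction of the
  lumen cloud); the basal plane passes through the first-turn centerline
  centroid; 0° points to the round-window-membrane centroid; handedness
  comes from the rotation sense of the lumen centerline, so angles increase
  base→apex for both ears and left/right phantoms yield identical scalar
  measurements. How the axis was located in the original manual workflow is
  not specified anywhere; this automated fit is validated only on phantoms
  (axis within 2°, zero direction within 3° of truth in the test suite).
* **Unwrapping.** Angular positions beyond 360° are disambiguated against
  the lumen centerline: each point picks the 360° branch whose expected
  centerline radius and height best match it. This is what lets a
  structure end at, say, 572° rather than 212°.
* **Centerline length.** No installed 3D thinning implementation exists in
  this toolchain, so the centerline is computed as geodesic-distance-binned
  centroids: Dijkstra over the 26-connected voxel graph (step weights 1,
  √2, √3 voxels), endpoints from a double farthest-point sweep, path =
  polyline through per-bin centroids (bin width 3 voxels). On tubular
  structures this matches closed forms well inside the 3–5% digitization
  tolerances (rod, helix and rotation-invariance tests); disconnected masks
  report the longest component plus a component count.
* **Local thickness.** Sphere fitting with diameters quantized to
  multiples of `step_voxels` (default 2, matching the scan protocol): a
  sphere of diameter $d$ voxels fits at $w$ when every voxel center within
  $d/2 + 1/2$ of $w$ is inside the mask — the half voxel accounts for the
  voxel footprint and makes the measure stable on oblique surfaces — and
  the largest fitting tested sphere is kept (floor quantization, the
  natural reading of testing diameters "in steps"). A 27-layer membrane
  therefore reads 26 voxels; at 6.3 µm a 0.17 mm membrane reads 0.1638 mm,
  within one voxel. Implementation is exact: per candidate diameter
  (descending), admissible centers are dilated by their radius via a
  Euclidean distance transform (Felzenszwalb–Huttenlocher, written in C++
  here since no installed R package provides a 3D EDT), and the test suite
  checks exact agreement with a brute-force pairwise oracle on random
  blobs. Structures thinner than one step still report one voxel, keeping
  the map positive on the mask.
* **Thickness histograms** weight by voxels (volume), not by surface area
  — whether the published "% of membrane area" was voxel-, surface- or
  projection-weighted is not stated; the voxel-weighted convention is
  flagged here and in the report files. Bin midpoints are exactly
  $(lo + hi)/2$; bins extend below the start edge when needed so
  percentages always total 100.
* **Dimensions.** Length/width/height are extents along the zero
  direction, its in-plane perpendicular, and the axis; measured extents
  include the outermost voxels' footprint (peak-to-peak centers plus one
  voxel), so raster measurements can exceed the continuous envelope by up
  to a voxel.
* **Trauma.** Per structure, the trauma mask is `pre == s & post != s &
  post != electrode`. Displacement (elevation/deformation) is told apart
  from removal by whether at least half the lost voxels reappear under the
  structure's label elsewhere; displaced basilar membrane maps to
  "BM elevation" (grade 1), removals map to the rupture/fracture
  descriptors, an electrode voxel whose pre-insertion label was scala
  vestibuli adds the grade-3 descriptor, and the composite grade is the
  maximum (the scale is ordinal). Deformation voxels count toward the
  affected fraction via the symmetric-difference convention, which the
  report header flags.

## Tomography and artifact reduction

The scanner's cone-beam reconstruction is emulated as its parallel-beam,
slice-wise specialization — the projection-completion algorithm is
geometry-agnostic, and parallel-beam keeps the simulation desk-scale and
exactly testable. Rays are sampled at voxel-size steps with bilinear
(Joseph-style) interpolation; the backprojector reuses the identical rays
and weights, so the pair is an exact adjoint (tested at 1e-4, observed at
rounding error). Filtering is a ramp with Hann apodization (cutoff
parameterizable) applied along detector rows via FFT; reconstruction is
linear, and a project-then-reconstruct cycle on a multi-disc slice stays
below 5% RMSE of the dynamic range at 360 views. Rotational invariance of
a centered disc's projections is exact only over the grid's 4-fold
symmetric angles; at intermediate angles it holds to grid-sampling error,
which is what any discrete projector gives.

Metal artifact reduction follows the simple projection-completion recipe:
FBP, threshold segmentation of metal (the threshold must exceed the
volume's median — below it, half the anatomy would be "metal"), forward
projection of the binary metal image, replacement of every sinogram pixel
with metal path length above 1e-9 by 1D linear interpolation between the
nearest unaffected pixels along its detector row, and a final FBP. Shadows
touching the detector edge extend as constants from the nearest unaffected
pixel; a fully occluded row is an error — more sophisticated recovery is
deliberately out of scope. Metal voxels are re-inserted from the initial
reconstruction by default so the electrode stays visible (a flag disables
this); whether the original workflow re-inserted them is unstated, so it
is configuration. On metal-free data the whole chain is bit-identical to
plain FBP, and on the electrode phantom the fluid-annulus streak metric
(grey-value SD at 5–15 voxels from metal) drops below half its uncorrected
value in the regression test.

## Grey-value conditioning

Windowing maps the 0.1/99.9 percentiles (hot-pixel-resistant defaults) to
0/255 monotonically. Cross-dataset normalization is the unique affine map
sending the two reference-material means to their targets (bone 220,
parafilm 60 by default) — two references determine exactly an affine map,
which is also why it is idempotent to within a grey level. Image quality
is tracked as the contrast-to-noise ratio between the reference materials
(difference of means over pooled SD). The 0–3 visibility grading is an
automated proxy for a human assessment: a structure voxel is visible when
its grey exceeds the same-turn fluid mean by a threshold (suggested: about
3× the fluid noise SD), assessment slices are 5° azimuthal sectors,
"entire" means ≥95% of voxels visible in a sector, and the grade is 3 when
entire on all sectors, 2 when partial on all, 1 when partial on some, 0
otherwise. These knobs are configuration, not a claim of equivalence to a
human grader; under the staining model the grades are monotone in
submersion time, which the test suite checks.

## Degenerate inputs and tie-breaks

Generation fails loudly on: non-positive turns, any structure thinner than
one voxel (naming it), an apical duct thinner than one voxel, infeasible
target dimensions, a cochlea larger than the field of view, or reference
blocks colliding with anatomy. Measurements error on empty structures
(absence is never silently 0), points on the modiolar axis (undefined
azimuth), constant volumes (zero dynamic range), equal reference means,
zero pooled SD, empty masks, and single-angle reconstruction. Lesions must
name known structures and stay within the electrode depth. Fractional
lesions take the basal-most fraction of in-range voxels (a deterministic,
contiguous tie-break); turn counts are reported to 0.1 turns as measured.

## Problem sizes

The test suite runs the reference phantom at 144³ voxels × 75 µm with
secondary phantoms at 120³ × 96 µm, chosen so the full suite (475
assertions) completes in about a minute and a half on one CPU; the
acceptance script uses the default 192³ × 56 µm phantom and the 6.3 µm
membrane patch and completes in well under a minute. Tolerances quoted
throughout (±0.05 turns, ±3° angles, 5% volumes and lengths, one-voxel
thickness and dimensions) are the rasterization-limited accuracies observed
at these sizes, not statements about scanner accuracy.

## Known limitations

The phantom is schematic: circular duct sections, slab membranes, no
organ-of-Corti microanatomy, no Reissner-membrane slope, monochromatic
attenuation without beam hardening or scatter, and parallel-beam rather
than cone-beam geometry (all deliberate non-goals). The staining model is
a two-parameter front and ignores diffusion through the modiolus and
precipitation effects. Frame fitting assumes a segmented modiolus or lumen
and is untested on clinical-resolution data. Pre/post trauma comparison
assumes the two label volumes share a grid — registration of independently
acquired scans is out of scope. The visibility grading automates a human
protocol and should not be compared grade-for-grade against human readers.
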