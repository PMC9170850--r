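---
title: "Quantifying aortic sodium fluoride uptake: TBR, AMA, and their validation on digital phantoms"
author: "amapet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic sodium fluoride uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amapet)
```

## The measurement problem

Sodium [18F]fluoride binds to developing microcalcification, so its PET
signal in the abdominal aortic wall reflects active disease in an
aneurysm. Turning that signal into a per-patient number runs into three
obstacles:

1. **Workload.** The conventional tissue-to-background ratio (TBR) is
   built from circular regions of interest drawn around the aorta on
   every trans-axial plane — accurate but slow.
2. **Vertebral spill-over.** The spine takes up fluoride avidly and sits
   directly behind the aorta. The scanner's point-spread function (PSF)
   smears that intense signal into the aneurysm, inflating any
   unprotected measurement.
3. **Changing caliber.** An aneurysmal aorta widens from roughly 1 cm
   radius at the neck to 2 cm or more at the bulge. A cylinder of fixed
   radius either clips aneurysm tissue or swallows extra-aortic tissue.

`amapet` implements both measurements and the two corrections, plus the
statistical battery used to compare them, and validates everything on
synthetic phantoms with known ground truth.

## Definitions

All voxel intensities are standard uptake values (SUV). The blood-pool
denominator is estimated from two 8-mm-radius spheres placed in the
cardiac blood pool: each sphere's *cumulative SUV* (the voxel-volume
weighted sum, SUV·cm³) is divided by the spheres' total volume, i.e. the
background is the volume-weighted mean voxel SUV over both spheres
combined. Defining cumulative SUV this way makes every later ratio
dimensionally clean: cumulative/volume is a mean SUV, so AMA and TBR live
on the same scale.

For a labeled aortic region (thoracic, suprarenal, neck, aneurysm):

- **TBR**: the region's slices are tiled into consecutive trans-axial
  slabs of 3 mm thickness (the last slab may be thinner), each slab
  masked by the per-slice aortic disk. `TBR_mean` is the unweighted mean
  of per-slab SUV_means divided by the background; `TBR_max` the maximum
  per-slab SUV_max divided by the background. Unweighted aggregation is
  the minimal assumption, and slabs are near-equal in volume by
  construction. An optional exclusion mask removes voxels contaminated by
  vertebral spill-over before slab statistics are taken.
- **AMA**: a tube is swept along the region's centerline; the VOI covers
  lumen, thrombus and wall. `AMA_mean = (cumulative SUV / volume) /
  background`, `AMA_max = SUV_max / background`.
- **Threshold**: a reference sphere is placed over the visually highest
  aortic uptake clearly distinct from the vertebra; its SUV_max becomes
  an upper voxel-intensity limit for the region. Voxels *strictly above*
  the limit are excluded from cumulative SUV, volume, mean and max. Ties
  at the limit are retained, so the defining sphere's own maximum never
  invalidates its region.
- **Variable radius**: with per-point radii annotated on the centerline,
  the tube's local radius follows the vessel; with the option off, the
  fallback is a fixed radius equal to the region's *maximum* annotated
  radius — deliberately mirroring the failure mode a uniform cylinder
  produces (inclusion of extra-aortic tissue), so the improvement is
  demonstrable.

The TBR aortic ROI is modeled as the full disk over the aortic
cross-section (lumen plus wall), not an annulus, because the AMA VOI it
is compared against also includes the lumen; a like-for-like comparison
requires the same cross-section. Whether slice ROIs should track the
luminal or adventitial contour is left as data — the per-slice disk
radius is an input, not a policy.

## Geometry and voxelization choices

- Physical coordinates are millimetres; voxel `(i, j, k)` (1-based) has
  its centre at `origin + (ijk - 1) * spacing`; z is the trans-axial
  slicing axis. Only axis-aligned NIfTI affines are accepted — oblique
  geometries would demand resampling decisions that are out of scope.
- Voxel inclusion is strictly **centre-in-geometry** with inclusive
  boundaries. There is no partial-volume weighting: masks are discrete
  voxel sets, reproducible, and checkable against an exhaustive
  brute-force loop (the test suite does exactly that).
- The tube has flat ends: a voxel belongs to the tube only if it projects
  perpendicularly onto some centerline segment, or falls in the wedge
  between two adjacent segments within the vertex's ball (which fills the
  outside of a bend). Vertex balls never extend past the terminal points,
  so a two-point centerline voxelizes to an exact right cylinder and
  adjacent region VOIs do not leak into one another axially. Ties between
  segments resolve to the earlier segment.
- The local radius is interpolated linearly in arc length between
  annotated points, evaluated at the arc-length position of the voxel's
  nearest point on the polyline. Linear interpolation is the minimal
  assumption given radii annotated at discrete points.
- Mask volumes converge to the analytic sphere/cylinder/frustum/disk
  volumes as spacing shrinks (tested at 2, 1 and 0.5 mm with strictly
  decreasing error); at 1 mm they agree within 3%.

## The digital phantom

`make_phantom()` builds a co-registered PET/CT pair with ground truth:

- a straight vertical aortic centerline whose radius follows a Gaussian
  bulge `r(z) = r_neck + (r_max - r_neck) * exp(-(z - z0)^2 / (2 s^2))`
  with `s = extent / 2.355` (the extent is a FWHM). Defaults: 10 mm neck,
  20 mm peak, 50 mm extent — a smooth nonlinear caliber change, precisely
  the condition that motivates the variable radius;
- a 3-mm wall/thrombus shell at `wall_suv` (default 2) around a lumen at
  `blood_suv` (default 1), on a zero background;
- a parallel vertebral column (single cylinder — only its spill-over
  field matters) at `vertebra_suv` (default 10, five times the wall), its
  surface a few millimetres from the aneurysm at its widest, as the
  aorta rests on the spine;
- a separate blood-pool cylinder hosting the two 8-mm background
  spheres. This stands in for the atria: the background must be sampled
  in a large blood volume whose signal does *not* scale with the
  pathology under study. (An earlier design that sampled the background
  inside the thoracic lumen let wall activity spill into the small lumen
  and made the measured background — and hence inversely the AMA — track
  the wall uptake itself.)
- PET is blurred with an isotropic Gaussian PSF (`psf_sigma_mm`, default
  4 mm) via separable, sum-normalised convolution, then Gaussian voxel
  noise (`noise_sd`, default 0.05 SUV) is added with a fixed seed. CT
  encodes the same geometry in Hounsfield-like values and is carried for
  landmarking only.

Default grid: 64 × 64 × 100 voxels at 2 mm — a 128 × 128 × 200 mm field
of view, desk-scale but big enough for 2-sigma blur margins everywhere.
Structures stay clear of all grid faces so blur conserves the image sum
to within 0.1%.

Ground truth records, per region: pre-blur SUV_mean/SUV_max, the region
z-bounds, the true aortic voxel mask, and the **spill-free reference** —
the same phantom blurred with the vertebra removed. The two references
answer different questions. Pre-blur truth anchors exact identities on
unblurred phantoms (where `AMA_mean = TBR_mean = tissue/blood` exactly).
The spill-free reference is the yardstick for the thresholding
correction: thresholding removes abnormally high voxels caused by
vertebral spill-over, but cannot restore signal the PSF has moved out of
the VOI. Judged against pre-blur truth, *any* blurred measurement of a
2-cm-calibre vessel underestimates by far more than spill-over adds
(partial-volume dilution is several tenths of an SUV at 4 mm sigma, the
spill bump a few hundredths), so the honest statement of what the
threshold achieves — and what the tests assert — is that the thresholded
AMA is closer to the spill-free blurred measurement than the
unthresholded AMA is.

For observer studies, `make_observer_replicates()` adds independent
Gaussian reader noise to a vector of per-subject values; its coefficient
of repeatability converges to `1.96 * sqrt(2) * sigma`, which the tests
verify in closed form.

What the phantom does *not* emulate: PET count statistics, scatter and
attenuation (noise is additive Gaussian after blur), tortuous
centerlines (the generator's axis is straight, though the tube voxelizer
itself handles bends and is tested on bent synthetic centerlines), soft
tissue background uptake, and respiratory or cardiac motion. Passing
phantom tests therefore demonstrates correctness of the geometry,
accumulation and statistics, not clinical performance on patient data.

## Statistical choices

- ICC is the two-way, consistency, single-measurement form — ICC(C,1).
  The two-way consistency model ignores systematic offsets between
  methods or readers, which is what a method-comparison of per-patient
  values wants; single-measurement is the standard choice when each
  patient is measured once per method. Mean squares come from the
  two-way ANOVA; the 95% CI is the standard F-interval for this form.
  With a perfect fit (zero residual) the estimate and interval collapse
  to 1 rather than passing NaN through the F machinery.
- Reliability bands are applied half-open: below 0.5 poor, [0.5, 0.75)
  moderate, [0.75, 0.9) good, 0.9 and above excellent. The half-open
  convention is documented because prose descriptions of these
  cut-points are ambiguous at the boundaries.
- Bland–Altman limits use 1.96 (not 2.0) and the n−1 sample standard
  deviation; percentage differences use the pairwise mean of the two
  methods as denominator.
- The coefficient of repeatability defaults to `1.96 * sd(differences)`;
  a within-subject ANOVA form `1.96 * sqrt(2) * s_w` is also provided,
  which additionally absorbs systematic bias. The two differ whenever
  bias is nonzero, and published values do not always say which was
  used, so both are exposed with the sd form as default.
- Region-level method comparisons use a paired two-sided t-test on the
  differences — the minimal test for a paired design.

## Problem sizes and runtime

The validation suite uses 2-mm phantoms of 64 × 64 × 100 (default) or
about 50 × 44 × 70 voxels (fast CLI fixtures), a 25-phantom cohort for
agreement statistics, 10 seeded phantoms for the spill-over property,
n = 500 simulated subjects for the repeatability closed forms, and 200
random 8 × 2 matrices for the ANOVA-by-summation oracle checks. The full
test suite runs in well under a minute; `scripts/acceptance.R` in under
one minute.

## Known limitations

- Inputs must be SUV volumes on axis-aligned grids; DICOM conversion,
  registration and SUV calibration happen upstream.
- The TBR slice model requires the centerline to be z-monotone within a
  region; strongly tortuous segments would need oblique reformatting,
  which the tool does not do.
- Thresholding removes spill-over voxels above the regional limit but
  cannot remove sub-threshold spill-over, and partial-volume dilution is
  uncorrected in both methods — ratios from blurred data sit below their
  pre-blur values by design of the physics, not of the software.
- Scan–rescan reproducibility is outside the package's scope; only
  method agreement and reader repeatability are modelled.
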