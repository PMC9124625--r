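---
title: "Methods: cord dose under setup errors and contour change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cord dose under setup errors and contour change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`cordshift`. The package quantifies two geometric uncertainties of
fractionated head-and-neck radiotherapy — regional setup errors of the
cervical spine and progressive shrinkage of the neck contour — through their
effect on the spinal-cord near-maximum dose, and implements a rapid
estimation method suitable for daily image-guided use.

## Coordinate and unit conventions

All geometry uses a fixed axis order: x = left–right, y = inferior–superior
(increasing towards the head), z = anterior–posterior (increasing
anteriorly), all in mm. Contours are simple polygons in axial x–z planes at
constant y. Areas are reported in cm², volumes in cm³ (cc), doses in Gy.
DICOM patient coordinates (LPS) are converted at the reader boundary:
internal (x, y, z) = patient (x, z, −y), and the mapping is logged.

A setup-error shift is *anatomy at treatment minus planned position* in plan
coordinates; the rapid estimator therefore **adds** the shift vector to the
planned cord contour. The source data only defines the test and the axes,
not the sign convention, so this is declared here and in the fixture format.

## Dose-volume metric

`D0.1cc` is computed discretely: in-mask voxel doses are sorted descending
(stable radix sort; ties therefore resolve deterministically), voxel volumes
accumulated, and the dose of the voxel at which the cumulative volume first
reaches the threshold is returned. `v = 0` degenerates to the plain voxel
maximum. No sub-voxel interpolation is applied; whether clinical planning
systems interpolate their DVHs is not specified by the source, so the
discrete convention is declared rather than claimed identical. The
definitional property — the returned dose is the largest d with
volume{dose ≥ d} ≥ v — is enforced against a brute-force oracle in the test
suite.

## Region partition and slice surface area

The cord is split into C1–C3, C4–C5 and C6–C7 by half-open intervals
[y_min, y_max); a contour exactly at a boundary belongs to the interval whose
y_min it equals. Vertebral boundaries are configuration inputs — the study
never gives them numerically; the phantom uses 60 / 35 / 40 mm extents
(superior to inferior), which are ordinary adult cervical proportions.

The slice surface area (SSA) of a region is the *median* polygon area over
the region's body-contour slices (mean of the two central values for even
counts). Contour change is (SSA_plan − SSA_day)/SSA_plan, positive for
shrinkage. Contour clipping scales each slice polygon radially about its
centroid by sqrt(1 − shrink), so the area change is exact by construction.
The source clips the planning external to the treatment-day external without
defining the geometry (its figure suggests posterior flattening); isotropic
area-matched scaling is this package's declared stand-in and is *not*
asserted to be the source's geometry. For the depth-driven toy dose engine
only the area (hence depth) change matters, so this choice does not affect
the qualitative dose structure.

Rasterization is voxel-centre, even–odd point-in-polygon, with a voxel
assigned to the nearest contour slice within half a slice pitch (the larger
of the grid pitch and the structure's own slice pitch). There is no
partial-volume weighting; the discretization error is bounded by the voxel
size and is verified to shrink with grid refinement on an analytic cylinder.
Multi-island slices are rejected (one polygon per slice per structure).

## The rapid estimation method

`dmax_displaced()` translates the planned cord contour of one region by the
measured regional shift and re-reads the *planned* dose grid. Numerically,
the planned contour is rasterized once and the resulting voxel centres are
rigidly translated, then the planned grid is sampled there by trilinear
interpolation. Two consequences are deliberate:

- a zero shift reproduces the planned value exactly (identical code path);
- sub-voxel shifts are resolved continuously, so on a linear dose ramp the
  estimate changes by exactly gradient × shift. Re-rasterizing the displaced
  contour on the fixed lattice would quantize sub-voxel shifts away and
  break that identity, which is why the translate-the-sampling-points
  convention was chosen.

Out-of-extent displacements raise a hard error naming the region rather than
clamping, to avoid silently underestimating dose. Shifts are applied per
region independently (each region is registered separately); there is no
blending at region boundaries.

The estimator is validated against the toy engine's full recalculation on
shifted anatomy (`Dmax_setup`) by pooled ordinary least squares across
regions — pooled because a single fitting formula should serve any region;
a per-region mode exists for inspection. The residual mean ± SD is reported
alongside slope, intercept and R².

## The toy dose engine

The engine is a declared model, not a clinical algorithm. Per axial slice,
N = 36 equally spaced coplanar beams contribute
w_b(p) · exp(−μ · depth_b(p)), where depth is measured from the external
surface along the beam axis (first boundary crossing towards the source;
exact for the convex sections used) and μ = 0.005 mm⁻¹ approximates a 6 MV
beam in water. The weight w_b is a fluence profile *fixed in room
coordinates*: a flat field with sigmoid penumbra (half-width 50 mm, penumbra
scale 6 mm) aimed at the target axis, multiplied by a Gaussian cord-sparing
notch centred on the *planned* cord axis. A purely anatomy-locked
depth-dose would translate rigidly with the patient and make setup shifts
dose-neutral; the room-fixed fluence gives the dose distribution the
beam-defined structure that image-guided radiotherapy actually has — the
cord sits in a dose valley, any shift climbs the valley walls, and body
shrinkage increases dose through reduced depth. Points outside the body
receive zero dose.

Normalization is fixed-monitor-unit: the notch-free reference dose at the
target axis equals the per-fraction prescription (70 Gy / 33) *on the
planning anatomy*, and that factor is reused unchanged for every perturbed
recalculation, as a planning system re-computing an unchanged plan would.

Notch widths are 9 / 14 / 24 mm for C1–C3 / C4–C5 / C6–C7: valleys flatten
inferiorly, encoding that the lower neck is farther from the high-dose
target and so sees flatter gradients. Notch depths are not hand-set: they
are calibrated (Gauss–Seidel sweeps of one-dimensional root finding) so the
planned regional D0.1cc hits the configured targets of 37.4 / 36.2 /
33.2 Gy — the per-region planned means the pipeline is designed around.

## The synthetic phantom and cohort

The phantom is an elliptical neck (AP/LR aspect 0.75) with a 4 mm-radius
cord cylinder 25 mm posterior of the body axis, sliced at 2.5 mm on a
2.5 mm dose lattice (the clinical grid size). Per-region body areas are
anchored at 192.7 / 133.0 / 171.4 cm² (the planning-CT cohort means) at the
region centres and cosine-blended along y, flat beyond the outermost
centres; the body and lattice extend 15 mm beyond the partitioned cord so
shifted contours stay on anatomy. The smooth taper matters: a
piecewise-constant profile puts dose discontinuities at region boundaries
that superior–inferior shifts turn into recalculation artifacts real necks
do not have. One consequence of blending is that the C4–C5 SSA median sits
slightly above its 133 cm² anchor (its neighbours are larger); the package
is self-consistent about this because every SSA it reports is measured from
the same polygons.

Setup errors are drawn per region and axis from Gaussians with an
early/late phase break at fraction 23. The per-axis parameters are
assumptions (the source reports only 3D magnitudes): isotropic SDs with a
negative AP mean (the posterior tendency of neck setup errors), solved so
the expected 3D magnitude matches the per-phase regional means — head 2.0 mm
throughout; C1–C3 2.1 → 2.7 mm; C4–C5 2.5 → 4.0 mm; C6–C7 2.8 → 4.2 mm.
Shrinkage is zero at the first imaged fraction and linear in fraction index
to per-region course-end fractions of 6.69 / 12.93 / 17.91% (the endpoint
area reductions), with per-patient end values drawn at relative SD 0.45
(truncated at zero) — course-end variability of that order is what the
reported cohort SDs imply. Imaging happens at fractions 1, 10, 17, 23, 28
and 33; per-fraction metrics are scaled to the course by multiplying by 33.

For each patient and imaged fraction three recalculations are made at the
cord's lattice voxel centres: *delivered* (shift + shrink), *setup* (shift
only, planning contour) and *contour* (shrink only). The setup and
delivered variants read D0.1cc on the lattice rasterization of the
*shifted* cord, which is what a planning system recalculating on shifted
anatomy does. Point evaluation at voxel centres is verified in the tests to
equal a full-grid computation masked to the same voxels.

What the generator does *not* emulate: between-patient anatomical
variability (all synthetic patients share the phantom and plan, so cohort
SDs reflect sampling variability only), non-Gaussian or correlated-in-time
setup errors, rotations, anisotropic (posterior-flattening) shrinkage,
heterogeneity, scatter, or arc delivery. Passing tests therefore
demonstrate the pipeline's internal correctness and the estimator's
validity *under this declared model*, not clinical performance.

A `contour_dose_model = "linear"` generator mode replaces the engine's
contour-only recalculation with an exactly linear dose response of known
slope (default 0.17% per % area change, plus Gaussian recalculation noise,
SD 0.1 percent points by default). Slope recovery is only a well-posed
check when the true response is exactly linear — the engine's exponential
depth response has mild curvature — so the parameter-recovery validation
uses this mode; the engine mode remains the default everywhere else.

## Statistics

Head-versus-region comparisons use the two-sided Wilcoxon signed-rank test,
paired on patient-fraction: zero differences are dropped (the classical
rule), the exact null is used for small samples without ties, and the
tie-corrected normal approximation otherwise. All paired differences being
zero raises a degeneracy error rather than returning p = 1. The
implementation is cross-checked against complete enumeration of the
signed-rank null for n ≤ 12. No multiple-testing correction is applied
(matching the original analysis).

The course-level "average contour change" is the mean over time points of
the cohort-mean fraction-wise changes. A `per_patient` mode (each record
against its own patient's baseline) exists because the two conventions
coincide only when patients share a baseline: with only cohort means as
input the per-patient value of the original tables cannot be reconstructed
exactly, and the cohort-mean convention reproduces the printed C1–C3 value
at printed precision while differing in the last decimal for the other two
regions.

Percent dose differences are always taken against the *region's own*
planned D0.1cc. Regressions are ordinary least squares with R² computed
from residual and total sums of squares (degenerate zero-variance
predictors raise a rank error; an exactly constant response defines R² = 1
when residuals vanish).

## Problem sizes and tolerances

The shipped study conditions are 10-patient courses with 6 imaging time
points and 3 cord regions (180 recalculations per variant) on a
77 × 66 × 59 lattice; the full planned grid takes tens of seconds and a
sampled course a couple of minutes on one CPU, which keeps the complete
suite and the acceptance script within routine desk-scale runtimes. Root
finding uses a 1e-5 tolerance on the notch depth (well inside the ±1 Gy
calibration contract); fixture JSON round-trips doubles to within one ulp
while grid arrays use a raw little-endian container and round-trip
byte-exactly.

## Known limitations

- The engine's surface dose is unphysically high (no build-up region); the
  package only ever evaluates cord doses, where the model is smooth.
- Convexity of body sections is assumed by the depth computation's
  first-crossing rule; the phantom and its clipped variants are convex by
  construction.
- The DICOM reader covers explicit-VR little-endian RTDOSE/RTSTRUCT with
  identity orientation and uniform frame spacing; anything else errors
  descriptively. It reads only — the package never writes DICOM.
- The replanning flag is a threshold rule on the displaced estimate; it is
  a screening aid, not a clinical decision.
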