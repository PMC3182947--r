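---
title: "Guide-point modelling of left-ventricular function from reduced-slice cine CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-point modelling of left-ventricular function from reduced-slice cine CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvgpm)
```

## The problem

Cine CMR quantification of murine left-ventricular (LV) mass and volumes
conventionally acquires a contiguous short-axis (SAX) stack covering the
whole ventricle — typically around ten 1 mm slices at 2–3 minutes each —
and sums manually segmented slice areas.  Acquisition time is the
bottleneck: it prolongs anaesthesia and limits throughput.  A 3D geometric
model of the LV that interpolates between slices can, in principle, deliver
the same global function parameters from far fewer slices.  This package
implements such a guide-point modelling (GPM) pipeline end to end —
synthetic data generation with analytic truth, the conventional
slice-summation reference, the model-based analysis, deterministic
slice-reduction rules, and the agreement statistics used to compare them.

## The surface model

Each surface (endocardial and epicardial) is a star-shaped radial field
about a fixed centre on the LV long axis,

$$ S(\mu, \theta) = c + \lambda(\mu, \theta)\, e(\mu, \theta), $$

where $e$ is the unit direction at polar angle $\varphi = \pi\mu$ from the
basal axis direction ($\mu = 0$ the basal pole, $\mu = 1$ the apex) and
azimuth $\theta$ about the axis.  The radius $\lambda$ (mm) is expanded in
a tensor product of clamped cubic B-splines in $\mu$ and periodic cubic
B-splines in $\theta$; the first and last rows of the coefficient grid are
tied to a single value so both poles close to well-defined points, and the
periodic basis makes the surface $C^2$ across $\theta = 0$.

The default basis is $8 \times 8$ coefficients per surface (50 free
parameters after pole tying).  Coarser grids were examined: with 4
longitudinal coefficients the radial profile of a mouse-scale truncated
ellipsoid cannot be represented to better than a few percent in derived
volumes, while $8 \times 8$ keeps end-systolic volume errors of noise-free
fits below 1% and still has few enough parameters that two SAX plus two LAX
slices constrain the fit.

## Fitting

Contours are mapped to 3D through their slice-plane geometry; long-axis
contour points basal to the frame's mitral-valve plane (the
total-least-squares plane through the four valve landmarks) are discarded.
Each data point is assigned the parameter location where its radial ray
from the model centre meets the surface.  For a star-shaped radial field
this assignment is exact and independent of the current coefficients, so
the classical alternating project/solve scheme converges after a single
refit; the outer loop and its parameter-motion stopping rule are retained
(and exercised by the diagnostics), but in practice two iterations suffice.

Given locations $(\mu_i, \theta_i)$ and radial data $r_i$, the coefficients
solve the penalized least-squares problem

$$ \min_\lambda \sum_i w_i\,(\lambda(\mu_i,\theta_i) - r_i)^2
   + \alpha_0 S_0[\lambda - \lambda_{\mathrm{ref}}]
   + \alpha_1 S_1[\lambda - \lambda_{\mathrm{ref}}]
   + \alpha_2 S_2[\lambda - \lambda_{\mathrm{ref}}], $$

with $S_1, S_2$ quadrature approximations of the integrated squared first
and second parametric derivatives and $S_0$ the zeroth-order (identity)
form.  Two design choices deserve emphasis:

* **Penalties act on the deviation from a reference field**, not on
  $\lambda$ itself.  The reference is the previous frame's fit (the
  deterministic initial ellipsoid for the first frame), which gives
  temporal coherence without an explicit temporal penalty.  Penalizing
  $\lambda$ directly would flatten the field wherever data are absent — in
  the basal region above the valve plane and between omitted slices — to
  the point where the surface no longer reaches the mitral-valve plane and
  no cavity volume can be defined.  Deviation penalties instead make
  unsampled regions follow the reference shape, which is precisely the
  model-interpolation behaviour that motivates reduced-slice protocols.
* **A weak zeroth-order term** ($\alpha_0 = 0.1$) anchors the absolute
  radius in unsampled regions; with thousands of contour points per frame
  at unit weight it is negligible wherever data exist.

Defaults $\alpha_1 = 10^{-3}$, $\alpha_2 = 10^{-2}$ (mm² per unit parameter
area) were chosen so that noise-free full-stack fits recover analytic
volumes to well under 1% while four-slice fits of symmetric phantoms stay
within a few percent.  The normal matrix is strictly positive definite for
any non-empty data set (the penalties' null space is removed by the data
term through partition of unity), and an epicardial field that dips inside
the endocardial one after fitting is repaired by a uniform outward shift
and logged.

The initial model is deterministic: the long axis runs from the
mitral-landmark centroid to the apex estimate (most apical SAX endocardial
contour centroid, extended half a slice), the endocardial radius is the
mean SAX contour radius about that axis, and the in-plane frame is derived
from the first valve landmark so the whole construction is equivariant
under rigid motions of the study.

## Volumes, mass and derived function

Cavity volume is the volume enclosed by the endocardial surface and the
mitral-valve plane, computed in spherical form: for each azimuthal
quadrature node the cut angle where the surface meets the plane is located
by root finding, and the radial bound — surface radius beyond the cut,
ray–plane distance before it — is integrated with composite Gauss–Legendre
rules on each smooth piece (relative error below $10^{-4}$ against
truncated-ellipsoid closed forms at order 8).  An independent voxel-counting
oracle (20 µm grid) is used in the tests.  LV mass is
1.05 mg/µl × (epicardial − endocardial volume); the GPM path averages the
wall volume over all frames, the standard path over its per-slice ED and ES
frames, mirroring the two methods' conventions.  GPM selects ED/ES as the
frames of global maximal/minimal model volume, whereas the standard method
selects them per slice — this deliberate difference is itself a documented
source of method disagreement.  Papillary muscles are by convention part of
the cavity; the phantoms contain none.

## The phantom generator

The synthetic studies emulate the geometry and acquisition of murine cine
CMR.  Surfaces are truncated ellipsoids: the control preset (endocardial
semi-axes 1.95/1.95/4.6 mm, 1.0 mm wall, basal plane at 0.55 of the long
semi-axis) yields EDV ≈ 64 µl, mass ≈ 108 mg and EF ≈ 59%; the infarct
preset (2.85/2.85/5.0 mm, 0.82 mm wall) yields EDV ≈ 168 µl, EF ≈ 18%, with
an anterolateral window combining a 0.35 mm outward bulge, 45% wall
thinning and frozen (akinetic) motion, tuned so the akinetic area is ≈ 39%
of the myocardial mid-wall surface.  Contraction follows a raised cosine
over 20 frames (frame 1 end-diastole, mid-cycle end-systole) with 35%
(control) or 18% (infarct) short-axis shortening and a few percent
long-axis shortening; the epicardial short radius is solved in closed form
each frame so wall volume is conserved over the cycle.  The akinetic
fraction is defined as the mid-wall area whose endocardial ED→ES radial
excursion is below τ = 0.1 mm, evaluated by area quadrature between the
basal plane and the apex.

Acquisition places SAX planes at 1 mm spacing from the basal plane toward
the apex (7–9 slices intersect the LV), adds the two orthogonal LAX planes,
intersects every surface with every plane, resamples contour points at
~0.15 mm arclength spacing (structures under ~1 mm circumference are treated
as unsegmentable and dropped), and adds isotropic in-plane Gaussian noise of
0.02 mm SD — about 0.4 of the 50 µm reconstructed pixel — to contour points
and valve landmarks alike.  All randomness derives from one seed.

What the phantoms do **not** emulate: image intensities and their
segmentation, papillary muscles and trabeculation, through-plane motion,
gating artefacts, and observer-dependent contouring bias.  Passing phantom
tests therefore demonstrates the geometric and numerical correctness of the
pipeline and the information content of slice subsets, not segmentation
robustness on real images.

The azimuthally broad akinetic window required to reach a ~39% akinetic
fraction has one important consequence: both LAX planes cross the infarct
core, so even the four-slice protocol observes the remodelled wall along
its whole length at four azimuths.  The four-slice mass overestimation on
infarcted phantoms is therefore present but modest (1–2 mg), clearest for
the largest infarcts — a sign-level, not magnitude-level, reproduction of
the large four-slice mass errors seen with real, azimuthally complex
infarcts.

## Slice-reduction rules

Slices "within the LV" are those with a non-empty end-diastolic endocardial
contour.  The six-slice rule drops the most basal and most apical LV
slices, keeps alternate interior slices starting from the second-most
basal, trims any surplus from the apical end, and fills any shortfall from
the remaining interior slices (most apical first) — for stacks whose length
admits no exact alternating solution the fill rule is this package's fixed
extension.  The four-slice rule keeps slices at 1-based positions
round(N/4) and round(3N/4), ties toward the base.  Reduction never alters
retained contours.

## Statistics

Bland–Altman limits are implemented literally as bias ± 2 SD (sample SD,
n − 1).  The repeated-measures ANOVA is the one-way within-subject
decomposition from explicit sums of squares, with sphericity assumed and
Bonferroni-corrected paired t post-hoc tests; for two methods F equals the
squared paired t statistic, which the tests verify along with the
Monte-Carlo type-I error rate at the 5% level.

## Numerical choices and degenerate inputs

Plane fitting uses orthogonal-distance regression via SVD, with coincident
points collapsed (≥3 distinct non-collinear points required) and the normal
oriented toward the apex.  Ties in per-slice ED/ES selection break toward
the earliest frame.  Slices whose cavity is empty in every frame are
excluded from ED/ES selection with a warning and use the stack-median
frames for their myocardial contribution.  Self-intersecting contour
polygons are a hard error naming the slice and frame.  Tangent or missing
plane/surface intersections yield an empty contour flagged degenerate
rather than an error; a basal plane that misses the surface, or cuts it
more than once along a meridian, is a geometry error.  Rasterized areas
count pixel centres on a lab-aligned grid (pitch 50 µm by default) inside
the contour polygon.

## Problem sizes used in the test suite

Unit tests run phantoms at 8 frames (end-systole falls exactly at
mid-cycle) and the voxel oracle at 40 µm; the end-to-end acceptance checks
use the full 20-frame, 50 µm-pixel conditions with the 20 µm voxel oracle
on the analytic ellipsoid.  These sizes are the package's reproducibility
baseline; all quantitative claims above are asserted by the test suite or
recomputed by `scripts/acceptance.R`.

## Known limitations

Frames are fitted independently (warm-started), so there is no explicit
temporal smoothing; the model centre and axis are fixed per study rather
than re-optimized per frame; infarct sizing from fitted (rather than truth)
surfaces inherits the fit's smoothing of the excursion field; and the
standard-analysis surrogate rasterizes noisy polygons rather than emulating
intensity-based segmentation.
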