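# lvgpm

Quantification of global left-ventricular (LV) function in mouse cine
cardiovascular MR (CMR) from contour-level data, built around
three-dimensional **guide-point modelling (GPM)**: a smooth parametric LV
surface model is fitted to sparse short-axis (SAX) and long-axis (LAX)
contour data, so that accurate mass and volumes can be obtained from far
fewer imaging slices than conventional slice-summation volumetry requires.
The package is aimed at small-animal CMR methodologists who want to study
reduced-slice acquisition protocols with a fully controlled, analytically
known ground truth.

## What it computes

For each analysis method the package reports end-diastolic and end-systolic
cavity volume (EDV, ESV, in µl), stroke volume SV = EDV − ESV, ejection
fraction EF = SV/EDV, and LV mass LVM = 1.05 mg/µl × myocardial volume.

Two analysis paths are implemented:

* **Standard slice summation** — a surrogate for manual voxel-count
  segmentation: per-slice rasterized contour areas, per-slice ED/ES frame
  selection (maximal/minimal cavity area), volumes as Σ area × slice
  thickness over the contiguous SAX stack.
* **Guide-point modelling** — each surface is a radial field λ(µ, θ) about
  the LV long axis, expanded in clamped cubic B-splines in µ × periodic
  cubic B-splines in θ, fitted per frame to 3D contour points by penalized
  linear least squares, with smoothing penalties on the deviation from a
  reference shape.  Cavity and wall volumes are computed by numerical
  integration of the fitted surfaces up to the mitral-valve plane (the
  total-least-squares plane through the four valve landmarks of the two
  LAX views).

Deterministic slice-reduction rules derive the **six-slice** (4 SAX + 2 LAX)
and **four-slice** (2 SAX + 2 LAX) protocols from a full study, and the
agreement machinery (Bland–Altman bias with ±2 SD limits, one-way
repeated-measures ANOVA with Bonferroni post-hoc tests) compares methods
across animals.

A parametric **beating-phantom generator** supplies synthetic studies at
mouse scale — truncated-ellipsoid surfaces, raised-cosine contraction,
optional infarcts with wall thinning, bulging and a frozen (akinetic)
region — together with analytic ground-truth volumes, mass and akinetic
fraction, and a simulated acquisition (SAX stack at 1 mm spacing, two
orthogonal LAX planes, Gaussian contour noise).

## Worked example

```r
library(lvgpm)

truth <- make_phantom(phantom_preset("control", rng_seed = 1))
truth
#> LV phantom truth: 20 frames
#>   EDV 63.8 ul  ESV 26.0 ul  SV 37.8 ul  EF 59.2%
#>   mass 107.9 mg  akinetic 0.0%  (ES frame 11)

study <- acquire_study(truth)          # 8 SAX slices + 2 LAX, 50 um pixels
slice_summation(study)                 # the standard analysis
#> LV function [standard]: EDV 64.0 ul  ESV 26.1 ul  SV 38.0 ul  EF 59.3%  mass 107.9 mg

analyze_gpm(study, "four")$report      # model-based, 2 SAX + 2 LAX only
#> LV function [gpm_four]: EDV 64.2 ul  ESV 24.7 ul  SV 39.4 ul  EF 61.4%  mass 107.7 mg
```

Even with only four slices the model-based analysis stays within a few
percent of the analytic truth on this symmetric ventricle; on infarcted
phantoms the four-slice protocol overestimates mass, which is the motivation
for keeping six slices when regional remodelling is present.

A thin command-line driver around these functions is installed at
`inst/scripts/lvgpm.R` (subcommands `simulate`, `analyze-standard`,
`analyze-gpm`, `reduce`, `run`).

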