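---
title: "Quantifying pulmonary fat attenuation volume and the pulmonary fat index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary fat attenuation volume and the pulmonary fat index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmofat)
```

## The measurement

Adipose-like tissue inside the lung is visible on CT as voxels whose
attenuation falls in the fat range of the Hounsfield scale. Given a chest CT
volume in HU and a co-registered lung mask, **pulmofat** quantifies:

* **CTpfav** (CT pulmonary fat attenuation volume): the physical volume, in
  mL, of lung-mask voxels whose HU lies inside a closed fat window,
  by default $[-200, -60]$ HU;
* **PFI** (pulmonary fat index):
  $$\mathrm{PFI} = \frac{\mathrm{CTpfav\,[mL]}}{\mathrm{lung\ volume\,[mL]}}
  \times 100\ (\%),$$
  which normalizes the fat volume for lung and body size. This matters
  because diseases that change fat content often change lung volume in the
  opposite direction (emphysema enlarges lungs, fibrosis shrinks them), so
  the raw volume alone is confounded.

Counting is deliberately literal: a voxel is wholly in or wholly out of the
fat compartment by its HU value. Partial-volume voxels at soft-tissue/air
interfaces can land in the window spuriously; this is a reported property
of the measurement, not something the package corrects. Vessels, airways
and endobronchial mucus are likewise not excluded. The window is closed on
both ends; the bound handling is isolated in one predicate
(`pulmofat:::in_window`), and both bounds are arguments everywhere because
the literature also uses an upper bound of $-40$ HU.

An empty lung mask is a hard error rather than a zero or `NaN`: a silent
zero PFI would flow into cohort statistics undetected.

## Geometry discipline

Masks are never resampled. The lung (or lobe) mask must live on exactly the
image grid: equal shape, spacing componentwise within $10^{-4}$ mm (header
float noise), identical orientation. Anything else is a refusal
(`validate_geometry()`), because resampling changes volumes — the very
quantity under study. Volumes are reoriented to one canonical axis
convention (RAS) at load; all reported quantities are orientation-invariant,
so this only standardizes bookkeeping.

## Subpleural and nonsubpleural compartments

Fibrotic disease deposits fat preferentially near the pleura, so the lung is
split at a depth of 1 cm from its surface. The split uses an exact signed
Euclidean distance map of the binary lung mask, computed in physical mm
with anisotropic voxel spacing honoured (a separable lower-envelope
transform; exact, not a chamfer approximation). Distances are
voxel-centre-to-voxel-centre: the magnitude at an interior voxel is the
distance to the nearest background voxel centre. A lung voxel is
*subpleural* iff that distance is $\le$ `depth_mm` (closed, so
boundary-adjacent voxels are always subpleural). Consequences of the chosen
conventions:

* The reference surface is the **entire** lung-mask boundary — costal,
  mediastinal, diaphragmatic and hilar alike. Nothing in the distance
  transform distinguishes pleural from hilar surface, and subsetting the
  surface would require anatomical landmarks the package does not have.
  Hilar inclusion is therefore a known sensitivity of the compartment
  definition.
* Both lungs are processed as one binary mask. For anatomically separated
  lungs this equals per-lung processing (verified by a dedicated test with
  two disjoint components).
* Interlobar fissures are never boundaries: the subpleural partition always
  uses the merged lung mask, so fissure-adjacent parenchyma is not
  "subpleural".
* The two compartments are an exact partition: voxel counts sum exactly,
  volumes to floating-point roundoff. An empty compartment (depth beyond
  the lung inradius) is reported with zero counts and an `NA` PFI.

## Lobar subanalysis

Per-lobe quantification uses the label convention
`c(LUL = 1, LLL = 2, RUL = 3, RML = 4, RLL = 5)` (configurable). Lobes are
aggregated as upper = LUL + RUL, middle = RML, lower = LLL + RLL, and the
group PFI is computed from **pooled** voxel counts,
$100\,\Sigma\,\mathrm{CTpfav} / \Sigma\,\mathrm{lungvol}$ — never the mean
of lobe PFIs, which would weight small lobes as much as large ones and
violate the PFI formula on the pooled region. Lobe masks need not tile the
lung (incomplete fissures are common); absent lobes are omitted from the
output rather than reported as zero.

## The synthetic phantom

Clinical scans cannot ship with a package, so every claim is validated on a
seeded synthetic phantom (`phantom_spec()` / `generate_phantom()`):

* two disjoint axis-aligned ellipsoidal "lungs" filled with aerated
  parenchyma at $-850 \pm 30$ HU, surrounded by soft tissue at $+40$ HU,
  with optional vessel cylinders at $+50$ HU;
* fat inclusions as non-overlapping spheres at $-100$ HU whose analytic
  volume $\Sigma \tfrac43\pi r^3$ is known exactly;
* planar lobe cuts along the cranio-caudal axis (a deliberate
  simplification of real fissure anatomy);
* optional i.i.d. Gaussian HU noise added after tissue assignment.

Rasterization is by voxel-centre inclusion, so the voxelized volume of a
sphere differs from the analytic volume by at most the surface-voxel count
times the voxel volume — the basis for every tolerance used in the tests.
Spec validation requires the parenchyma mean to sit at least 4 combined
standard deviations below the fat window and soft tissue at least 4 noise
standard deviations above it, which makes false fat voxels from noise
negligible and boundable. Ground truth (fat/lung voxel counts, per-lobe and
per-compartment fat) is computed from the shape equations only — never from
HU values — so agreement between the quantifier and the ground truth is a
genuine two-route cross-check.

What the phantom does **not** emulate: correlated CT texture and
reconstruction kernels, airway trees, realistic fissures, partial-volume
blur at interfaces, or scanner calibration error. Passing tests therefore
demonstrate the correctness of the counting, distance and statistics
machinery under controlled attenuation distributions, not robustness to
real-scan artefacts.

Placement constraints (`subpleural_within_mm`, `deeper_than_mm`, `lobe`)
are enforced during rejection sampling against the *analytic* distance to
the lung surface, obtained from the Lagrange condition for the nearest
point on an ellipsoid, solved by monotone bisection (the unique root of
$\sum_i a_i^2 y_i^2/(a_i^2+t)^2 = 1$ on $(-\min a_i^2, \infty)$ gives the
closest surface point for interior and exterior points alike). Exactly
on-axis points are degenerate for that parametrization and are nudged by
$10^{-9}$ mm, far below any tolerance in use. A constraint that cannot be
satisfied within a bounded number of draws is an explicit error.

## The cohort simulator

`generate_cohort()` emulates a three-group design: controls at a median PFI
target of 1.0%, an emphysema-like group at 0.5% with lungs scaled +15%
linearly (≈ 1.5× volume), and a fibrosis-like group at 2.0% with lungs
scaled −8%. The targets follow the magnitudes reported for such cohorts;
the spreads are the package's own choice — lognormal per-subject targets
with the widest spread (sdlog 0.45) for the fibrosis-like group and the
narrowest (0.15) for the emphysema-like group, mirroring the relative IQR
widths seen clinically. Each subject's fat load is built from r = 3 mm
spheres (plus one remainder sphere) placed uniformly in the lung until the
sampled target volume is reached, and the full HU-threshold pipeline is
then run on the phantom — the cohort table is produced by the measurement,
not copied from the targets. The default template is a $72^3$ grid at
1.5 mm isotropic spacing (lungs ≈ 130 mL), which keeps a 90-subject
simulation under half a minute while leaving sphere voxelization error well
below the group separation being tested.

## The statistics battery

`run_battery()` mirrors the standard analysis sequence for such cohorts:

1. **D'Agostino–Pearson** $K^2 = Z_{skew}^2 + Z_{kurt}^2$ per group
   (chi-square, 2 df), using D'Agostino's skewness and the Anscombe–Glynn
   kurtosis transformations. The transforms are undefined below $n = 8$
   (hard error) and the chi-square approximation is weak below $n = 20$
   (warning). Normality results are always reported but never used to
   switch methods — the battery always takes the nonparametric path.
2. **Kruskal–Wallis** omnibus H with tie correction (chi-square, $k-1$ df).
   The all-ties case is defined as $H = 0$ rather than $0/0$.
3. **Dunn's post hoc** pairwise z from pooled-rank mean differences with
   tie-corrected variance; two-sided p-values; Bonferroni-style adjustment
   (multiply by $k(k-1)/2$, cap at 1) by default. The exact multiplicity
   adjustment used by point-and-click packages is rarely printed, so the
   adjustment is an exposed option (`p.adjust` methods).
4. **Descriptives**: median and quartiles by linear interpolation between
   order statistics (type-7 quantiles — a convention choice, isolated in
   `describe_quartiles()`), reporting both the $(q_1, q_3)$ range and its
   width, since cohort tables print both styles.

Calibration is tested by Monte Carlo: under exchangeable nulls the omnibus
rejection rate at $\alpha = 0.05$ must land in $[0.03, 0.07]$ with
1000–2000 replicates, and both H and the Dunn z values are checked against
independently hand-rolled rank computations on small inputs.

## Numerical choices and degenerate inputs

* Distance transform: exact squared-distance propagation per axis; `Inf`
  rows (no feature on a scanline yet) are skipped in the envelope
  construction. Empty and full masks are errors — a boundary must exist.
* Geometry tolerance: spacing differences $\le 10^{-4}$ mm are treated as
  header noise; orientation must match exactly.
* PFI at machine precision: `pfi_pct` is stored as
  `100 * ctpfav_ml / lung_volume_ml` with no rounding; the identity is
  asserted at $10^{-12}$ relative across the test suite.
* DICOM input: slices sorted by position along the normal of the image
  orientation; slice gaps non-uniform beyond 1% are an error (the volume
  would be ill-defined); missing rescale slope/intercept tags are an error
  (identity is never assumed); only uncompressed little-endian transfer
  syntaxes are read.
* Seeding: every stochastic component (phantom noise, placement sampling,
  cohort draws) flows from an explicit integer seed; the same spec and seed
  reproduce outputs bit-identically. RNG state of the calling session is
  saved and restored.

## Problem sizes

Defaults are sized for interactive use and continuous testing: $96^3$
voxels at 1 mm for single phantoms (≈ 0.9 M voxels, distance map well
under a second), $72^3$ at 1.5 mm for cohort templates, and 10–32 voxels
per axis for the masks compared against the brute-force distance oracle.
Larger grids work unchanged; memory scales as a few doubles per voxel.

## Known limitations

* The fat window is a proxy: dual-energy material decomposition, scanner
  calibration and partial-volume modelling are all out of scope.
* The subpleural definition includes the hilar surface (see above).
* Lobe cuts in the phantom are planes, not fissures; the middle-lobe
  geometry in particular is not anatomical.
* The DICOM reader is intentionally minimal; production archives with
  compressed transfer syntaxes should be converted to NIfTI first.
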