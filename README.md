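# pulmofat

Fully automated quantification of **CT pulmonary fat attenuation volume
(CTpfav)** and the **pulmonary fat index (PFI)** from chest CT.

## What it measures, and for whom

Fat-isodense tissue inside the lung — seen histologically in fibrotic lung
disease and altered in emphysema — shows up on CT as voxels in the fat
attenuation range of the Hounsfield scale. Given a chest CT volume (NIfTI,
or an uncompressed DICOM series) and a co-registered lung mask, the package
computes

```
CTpfav [mL]  =  (# lung voxels with HU in [-200, -60]) x voxel volume
PFI [%]      =  CTpfav / lung volume x 100
```

with the fat window closed on both ends and configurable (the literature
also uses an upper bound of −40 HU). On top of the whole-lung numbers it
reports

* a **subpleural vs nonsubpleural** split at 1 cm depth, computed from an
  exact signed Euclidean distance map of the lung mask in physical mm
  (anisotropic spacing honoured), and
* a **lobar subanalysis** (per lobe, and pooled upper/middle/lower groups)
  from a lobe label mask.

It is aimed at imaging researchers studying pulmonary fat as a biomarker
(fibrotic ILD, COPD, controls). Lung and lobe segmentation are inputs —
produce them with your segmentation tool of choice; the package refuses
masks that are not on exactly the image grid rather than resampling.

Because clinical scans cannot be redistributed, the package ships a
deterministic **synthetic phantom generator** (ellipsoidal lungs, fat
spheres of analytically known volume, ground-truth masks) and a **cohort
simulator**, plus the standard **nonparametric cohort battery**:
D'Agostino–Pearson normality, Kruskal–Wallis omnibus, Dunn post hoc with
multiplicity adjustment, and median/IQR descriptives.

## Worked example

A 96³ phantom at 1 mm isotropic spacing with one r = 10 mm fat sphere
(analytic volume 4/3·π·10³ = 4.18879 mL) and Gaussian HU noise:

```r
library(pulmofat)

spec <- phantom_spec(
  fat = list(list(center = c(24, 48, 48), radius_mm = 10, hu = -100)),
  noise_sd = 15, seed = 42)
ph <- generate_phantom(spec)
ph
#> Synthetic CT phantom: 96 x 96 x 96 voxels @ 1 x 1 x 1 mm
#>   lung 91.66 mL, fat (analytic) 4.1888 mL, fat (voxelized) 4.2240 mL, 1 fat sphere(s)

compute_ctpfav(ph$image, ph$lung)
#> CTpfav: 4.2130 mL (4213 voxels)
#> Lung volume: 91.6640 mL (91664 voxels)
#> PFI: 4.5961 %  [window -200..-60 HU]

compartment_quant(ph$image, ph$lung, depth_mm = 10)
#> Subpleural compartment (depth 10 mm):
#> CTpfav: 2.4000 mL (2400 voxels)
#> Lung volume: 84.8000 mL (84800 voxels)
#> PFI: 2.8302 %  [window -200..-60 HU]
#> Nonsubpleural compartment:
#> CTpfav: 1.8130 mL (1813 voxels)
#> Lung volume: 6.8640 mL (6864 voxels)
#> PFI: 26.4132 %  [window -200..-60 HU]
```

Reading the numbers: the measured CTpfav (4.213 mL) sits within 1% of the
analytic sphere volume — the residual is voxel-centre rasterization plus a
handful of fat voxels pushed out of the window by noise. The lung volume is
the voxel count times 0.001 mL. PFI is high here only because the phantom
lung is small (92 mL vs several litres in vivo); on clinical-scale lungs the
same fat volume gives a PFI well under 1%. The sphere sits at the centre of
the left lung, so most of it lies deeper than 1 cm — hence the nonsubpleural
compartment, though only 7% of the lung by volume, holds 43% of the fat.

Real data goes through the same functions (`load_volume()`, `load_mask()`,
`compute_ctpfav()`, …) or through one call:

```r
run_pipeline(run_config(), "ct.nii.gz", "lung.nii.gz", "lobes.nii.gz",
             out_path = "result.json")
```

A cohort table (one row per subject) feeds the statistics battery:

```r
sim <- generate_cohort(n_per_group = 30, seed = 42)
run_battery(sim$table, "pfi_pct")
#> Kruskal-Wallis: H = 69.92, df = 2, p = 6.57e-16
#> Dunn post hoc (bonferroni-adjusted):
#>   control vs COPD: z = 4.611, p_adj = 1.2e-05 *
#>   ...
```

A command-line front end with the same functionality (subcommands
`quantify`, `partition`, `phantom`, `cohort-sim`, `cohort`) is installed at
`system.file("cli", "pulmofat.R", package = "pulmofat")`.

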