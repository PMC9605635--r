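# gliopet

PET/MRI radiomic feature extraction and prognostic modelling for
high-grade glioma.

Choline-PET uptake in IDH-wild-type high-grade glioma carries prognostic
information beyond the classical SUV statistics: how spherical the lesion
is, whether the disease is multifocal, and where the metabolic hotspot sits
relative to the tumor centre all track the invasiveness of the tumor.
`gliopet` implements that feature set as a tested, reusable pipeline for
3D PET SUV maps and contrast-enhanced T1 MRI volumes, together with the
survival analysis that links the features to outcome. Because clinical
scans are rarely shareable, the package also ships a synthetic phantom
generator and a proportional-hazards cohort simulator with known ground
truth, so every stage is verifiable end to end without any data download.

## What it computes

Per lesion (largest lesion when there are several), from a threshold-based
3D segmentation with N active and N' enclosed necrotic voxels of volume
Vv:

* **SUV statistics** — SUVmax, SUVmean, SUVpeak (maximum of the SUV field
  convolved with a 3×3×3 kernel of weights 1/27, i.e. each voxel averaged
  with its 26 neighbours), MTV = N·Vv, TLA = SUVmean·MTV.
* **Heterogeneity** — COV = σ_SUV / SUVmean (population σ); lesions with
  COV ≥ 0.30 are heterogeneous.
* **3D shape** — total volume V = (N+N')·Vv; triangulated-isosurface
  area S; sphericity Sg = π^(1/3) (6V)^(2/3) / S; maximum 3D diameter
  maxD; spherical rim width δs = (3V/4π)^(1/3) − (3V_inner/4π)^(1/3).
* **Peak-to-centroid distances** — the segmentation centroid
  (x_c, y_c, z_c) is the unweighted mean of the active voxel positions;
  SmCD and SpCD are the Euclidean distances from the SUVmax voxel and the
  SUVpeak cube centre to that centroid (mm); the mean spherical radius
  MSR = (3V/4π)^(1/3) normalizes SpCD into nSpCD = SpCD/MSR, ≈0 for a
  central hotspot and ≈1 for a boundary hotspot (peripheral when
  nSpCD ≥ 0.66 by default).
* **Multilesionality** — foci are 26-connected components at the
  segmentation threshold; two or more foci connected by faint elevated
  background uptake (a lower threshold) are multifocal, unconnected foci
  multicentric; both count as multilesional.

Per cohort: Pearson correlation of PET vs MRI features, median
dichotomization of OS/PFS with Welch t-tests, ROC curves with
Youden-optimal cutoffs, Kaplan–Meier/log-rank, and univariate plus
multivariate Cox models (Efron ties; sphericity reported per 0.1 increase).

## Worked example

A 10 mm lesion with a 4 mm necrotic core and a hotspot planted at 70% of
the radius, segmented at 40% of SUVmax:

```r
library(gliopet)

spec <- phantom_spec(
  grid_shape = c(48, 48, 48), spacing = c(1, 1, 1),
  lesions = lesion_spec(center = c(24, 24, 24), base_radius = 10,
                        necrotic_core_radius = 4,
                        hotspot_radial_fraction = 0.7,
                        hotspot_suv = 4.5, rim_suv = 3),
  background_suv = 0.3, noise_sd = 0.02, seed = 42)
ph <- make_phantom(spec)

ls <- segment_threshold(ph$grid, list(fraction_of_max = 0.40))
extract_lesion_features(ph$grid, ls)
#>   suv_max suv_peak mtv_ml   tla   cov sphericity msr_mm spcd_mm nspcd
#> 1    4.52     4.16   3.91  11.9  0.05       1.01   9.98    7.14 0.715
```

The phantom is recovered faithfully: MTV 3.91 mL plus 0.26 mL of necrotic
core against an analytic total of 4.19 mL, sphericity ~1 for a sphere,
MSR ~10 mm, and nSpCD 0.715 ≈ the planted 0.7 (classed `peripheral`; the
uniform rim makes the lesion `homogeneous`, COV 0.05).

The cohort simulator and Cox stage close the loop on the survival side —
hazard ratios used to generate a 500-patient cohort are recovered by the
multivariate fit:

```r
cohort <- simulate_cohort(cohort_sim_spec(n = 500, seed = 1))
cox_models(cohort, "os",
           multivariate = c("age", "stupp_incomplete",
                            "multilesional", "sphericity"))
#>   variable            hr ci_low ci_high        p     (truth)
#> 1 age              1.05   1.04    1.06  2.1e-24     1.044
#> 2 stupp_incomplete 2.73   2.24    3.34  4.4e-23     2.813
#> 3 multilesional    2.14   1.76    2.61  5.0e-14     2.203
#> 4 sphericity       0.759  0.709   0.813 3.0e-15     0.788 per tenth
```

A thin command-line wrapper with `phantom`, `simulate-cohort`, `extract`,
`analyze` and `all` subcommands lives at `inst/cli/gliopet`.

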