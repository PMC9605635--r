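---
title: "Methods: PET/MRI radiomics and prognostic modelling in gliopet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET/MRI radiomics and prognostic modelling in gliopet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliopet)
```

`gliopet` extracts SUV-based and 3D geometric radiomic features from PET
(and contrast-enhanced T1 MRI) volumes of high-grade glioma and links them
to survival. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish.

## Coordinate and unit conventions

A volume is a 3D scalar array plus a physical voxel spacing (mm per axis)
and the world position of the first voxel centre. Voxel `(i, j, k)`
(0-based) sits at `origin + (i, j, k) * spacing`; all centroids, distances
and surfaces are computed in this world frame, so anisotropic voxels are
handled without further thought. Everything internal is millimetres
(mm, mm², mm³); only the reporting layer converts to the clinical units —
volumes in mL, surfaces in cm², diameters and rim widths in cm — because a
single internal unit prevents silent unit mix-ups. NIfTI is the exchange
format; spacing is taken from the header and is the only header field
used, since every quantity in the pipeline is translation- and
rotation-frame invariant. DICOM handling, SUV calibration from raw
activity, and voxel-level PET/MRI co-registration are out of scope.

## Segmentation

Lesions are segmented by thresholding: either an absolute intensity or a
fraction of the volume maximum (PET default 0.40, a common delineation
practice; every downstream quantity is threshold-parameterised, so the
default is a configuration value, not a constant). Foreground voxels
(`>=` threshold) are split into 26-connected components; components below
`min_voxels` (default 10) are treated as noise speckles and dropped.
Labels are ordered by size, so label 1 is always the largest lesion.

The *inner* (necrotic) region of a lesion is defined as the interior holes
of its component: sub-threshold voxels unreachable from the array border
under 6-connectivity flood fill, i.e. hypointense/low-uptake tissue fully
enclosed by the lesion. The asymmetric connectivity pair (26 for lesions,
6 for holes) merges lesions permissively but keeps the necrosis definition
conservative. With several lesions, all per-lesion measures are computed
on the one maximising the *filled* volume `(N + N') * Vv`, ties breaking
to the lowest label.

The MRI analogue of the interactive "choose the gray level that maximises
the enhancing component" step is deterministic here: candidate thresholds
between the intensity median and 95% of the maximum are scanned and the
one giving the largest connected component is kept.

PET total volume is defined as the filled support `(N + N') * Vv`. The
distinction between metabolically active volume (MTV, active voxels only)
and total volume (hole-filled) matters once necrosis exists; the filled
definition is used consistently for sphericity, MSR and rim width, because
those are descriptors of the whole lesion, not of its active shell.

### Multifocal vs multicentric

Foci are components at the segmentation (high) threshold. One focus is
unifocal disease. With two or more foci the volume is re-thresholded at a
low level representing "faint elevated background uptake"; foci sharing a
low-threshold component are connected by faint uptake and classed
multifocal, otherwise multicentric. Both are `multilesional = TRUE` for
statistics. The low threshold defaults to mean + 2 SD of the outermost
voxel shell of the volume — an operational, testable stand-in for a
qualitative visual judgement; it can be overridden by an explicit rule.

## SUV features

* **SUVmax / SUVmean / σ** are computed over the active voxels only.
  σ uses the population convention (divide by N): COV is a descriptor of
  the voxel intensity distribution, not a sample estimate, and the choice
  makes the two-voxel example `{2, 4} -> σ = 1` unambiguous.
* **SUVpeak** filters the *whole* SUV field with a 3×3×3 kernel of
  weights 1/27 (each voxel averaged with its 26 neighbours, defined on
  voxel indices, not physical mm) and takes the maximum of the filtered
  field over the lesion. Neighbours outside the segmentation but inside
  the image do contribute to the average; only the arg-max search is
  mask-restricted. The border is zero-padded, consistent with a plain
  convolution; phantoms keep lesions at least 3 voxels from the border so
  the padding choice is immaterial in validation. The arg-max location —
  the cube centre of the SUVpeak calculation — is the reference point for
  SpCD; exact ties resolve to the first voxel in array order.
* **COV** = σ/SUVmean, heterogeneous iff COV ≥ 0.30 (the boundary value
  0.30 is heterogeneous).
* **MTV** = N·Vv (mL) and **TLA** = SUVmean·MTV.

## Geometric features

* **Surface.** The filled mask is smoothed with a 3×3×3 box filter and the
  0.5 level set is triangulated by marching tetrahedra (six tetrahedra per
  cell sharing the main diagonal; linear edge interpolation); the area is
  the sum of triangle areas in physical mm². Meshing the *raw* binary mask
  tracks the voxel staircase and overestimates a sphere's area by roughly
  28%, which would systematically depress sphericity; the smoothed level
  set tracks the underlying boundary (sphere r = 10 mm: +0.15% at 0.5 mm
  spacing, −0.7% at 1 mm — both recomputed by the test suite and the
  acceptance script). For lesions only a couple of voxels wide the
  smoothed field never reaches 0.5; the mesher then falls back to the raw
  mask so the area stays defined.
* **Sphericity** `Sg = π^(1/3) (6V)^(2/3) / S` with V, S in consistent
  units; 1 for a sphere (the mesh introduces ≤ 2% discretization
  tolerance), decreasing toward 0 with irregularity.
* **maxD** is the exact maximum pairwise distance between surface-voxel
  centres (surface voxel = mask voxel with a face-adjacent background
  neighbour), computed by a chunked scan; a single voxel has maxD 0 by
  convention.
* **Centroid** is the unweighted mean of the active voxel centres. An
  SUV-weighted variant would answer a different question (centre of
  metabolic mass); the geometric definition is the reference for the
  distance family and necrotic voxels are excluded from it.
* **SmCD / SpCD** are Euclidean distances (mm) from the SUVmax voxel and
  SUVpeak cube centre to the centroid. **MSR** = `(3V/4π)^(1/3)` uses the
  *total* (filled) volume — necrosis is part of the lesion's size — and
  **nSpCD** = SpCD/MSR. The peripheral/central cut defaults to 0.66, a
  cohort mean in the motivating data; a new dataset should recompute its
  own mean rather than inherit this constant.
* **Spherical rim width** δs is the difference of equivalent spherical
  radii of the total and inner volumes; with no inner volume it equals the
  MSR. This is an interpretive implementation of a "spherical
  approximation of the average rim size" and is exact for concentric
  spherical shells (an exact 5–10 mm shell gives 5 mm).

## Synthetic phantoms

Phantoms exist so every stage has known ground truth. A lesion is a
radially perturbed sphere: surface radius `R(u) = r (1 + b g(u))` along
direction `u`, where `g` is a smooth band-limited random angular function
(six cosine modes of unit-vector projections, wavenumber 3, normalised to
max |g| = 1) and `b` is the `bumpiness` amplitude. `b = 0` is an exact
discretised sphere with analytic volume `(4/3)πr³`; increasing `b` along a
fixed angular seed yields a family of increasing irregularity on which
sphericity decreases monotonically — the controllable axis behind the
sphericity–hazard link. A central core of radius `r_core < r` is rendered
at background intensity (low uptake / hypointense), giving necrosis ground
truth. A hotspot is an isotropic Gaussian bump (σ = 2 voxels) added to the
rim uptake *inside the active tissue only*, peaking at the stated SUV at a
point placed at `hotspot_radial_fraction × r` along a seeded random
direction — the planted nSpCD. Noise is additive Gaussian truncated at 0,
the simplest model sufficient to exercise threshold robustness.

Default rendering conditions: background SUV 0.3, rim SUV 3, hotspot SUV
4.5, noise SD 0.02 on 64³ grids at 1 mm spacing — values in the range of
clinical choline-PET background/tumor contrast, chosen once and used
throughout the validation. Bridged phantoms add a corridor (radius 1.5
voxels) of intermediate intensity between two lesion centres; the contract
`background < bridge < min(rim)` guarantees the foci are separate at the
high threshold and connected at the low one, which is precisely the
multifocal signature.

What the phantoms do *not* emulate: scanner point-spread and
partial-volume effects, Poisson-like PET noise, MRI bias fields, and
infiltrative (non-star-convex) tumor margins. Passing the recovery tests
therefore shows the estimators are correct on well-posed geometry, not
that they are robust to every clinical artefact.

## Cohort simulation

Survival times follow a Weibull proportional-hazards model
`S(t|x) = exp(−(t/λ)^k e^{lp})` with shape `k = 1.2`, scale `λ = 15`
months (reference-patient median `λ ln2^{1/k} ≈ 11` months, matching the
motivating cohort's median OS) and linear predictor

```
lp = log(1.044) (age − 61.44) + log(2.813) [Stupp incomplete]
   + log(2.203) [multilesional] + log(0.788) (sphericity − 0.63)/0.1
```

with covariates drawn as age ~ N(61.44, 12.64) truncated to [18, 90],
P(Stupp complete) = 0.63, P(multilesional) = 0.333, sphericity ~
N(0.63, 0.14) truncated to (0, 1]. Covariates are centred at their
generating means so the baseline scale keeps its reference-patient
interpretation; centring shifts only the baseline hazard and leaves every
hazard ratio, and hence all recovery tests, unchanged. Progression uses
the same linear predictor with the scale shrunk by 5/11 (median PFS 5 vs
OS 11 months) and `pfs = min(progression, death)`, so PFS never exceeds
OS. Censoring is administrative at the empirical `(1 − censor_rate)`
quantile of the drawn death times (default rate 0.11, matching 48/54
observed deaths), which is reproducible and hits the requested rate
exactly in-sample. Inert clinical covariates (ECOG, resection, Ki-67 with
its 20% high/low cut, WHO grade) are drawn from the motivating cohort's
frequencies so the table has a realistic schema.

## Statistical stage

Dichotomization splits patients at the endpoint-time median with ties in
the `<=` group; Welch's t-test is the default (the pooled-variance variant
is a flag) and Kolmogorov–Smirnov normality checks are reported as flags,
not gates. ROC curves are empirical, with trapezoidal AUC — equal to the
Mann–Whitney U statistic over n₁n₂, which the tests verify — and the
operating cutoff maximises Youden's J, ties resolving to the lowest
cutoff; the cutoff criterion is an interpretive choice documented here.
Kaplan–Meier and the log-rank (Mantel–Cox) test come from the `survival`
package, as do Cox models with Efron tie handling (accurate for
month-resolution ties). Sphericity enters Cox models divided by 0.1 so its
hazard ratio reads "per tenth of increase". No multiple-testing correction
is applied by default, mirroring common practice in small imaging cohorts;
p-values are reported raw and should be read accordingly.

## Validation sizes and determinism

The test suite and `scripts/acceptance.R` regenerate everything from code:
sphere/shell calibration at 0.5–2 mm spacings, SUVpeak against a
brute-force 27-neighbourhood oracle on 200 random 9³ grids, nSpCD recovery
at planted fractions {0, 0.25, 0.5, 0.75, 0.9} (r = 15 mm, 1 mm spacing,
tolerance ±0.1 — about one voxel of slack plus the inward pull the
mask-restricted filtered maximum feels near the boundary), 20 seeded
phantoms per multilesionality class, Cox recovery on 100 replicates of
n = 500 with 95% CI coverage counted, and a 400-replicate null for test
size. These sizes give stable pass/fail behaviour at interactive runtimes;
all randomness flows from explicit integer seeds, and phantom generation
restores the caller's RNG state.

## Known limitations

* Threshold segmentation assumes a hypermetabolic lesion on a colder
  background; diffuse or barely-enhancing disease (excluded from the
  motivating cohort's MRI arm too) will not segment meaningfully.
* nSpCD ground-truth recovery degrades as the hotspot approaches the
  boundary, where the neighbourhood average is pulled inward; the ±0.1
  tolerance reflects this.
* The phantom family is star-convex by construction; sphericity values
  below ~0.5 (bubble-chain morphologies) are outside the generator's
  reach, although the estimator itself handles arbitrary masks.
* The cohort simulator draws sphericity as a covariate rather than
  deriving it from a rendered phantom per patient; the end-to-end pipeline
  joins image-derived features to outcomes, but the hazard link in
  simulation is distributional, not image-mediated.
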