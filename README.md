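# mopet

Multi-level Otsu PET tumor segmentation and method-agreement statistics.

## The problem

Metabolic tumor volume (MTV) — the volume of tissue whose FDG-PET uptake
(in standardized uptake value, SUV, units) exceeds a segmentation
boundary — is a prognostic imaging biomarker, but its value depends
heavily on how the boundary is drawn. The common clinical recipes are an
absolute SUV cut (e.g. SUV ≥ 2.0), a fixed percentage of the lesion's
SUVmax (e.g. ≥ 30% · SUVmax), or a gradient-based edge search. Absolute
cuts fail on low-uptake lesions, percentage cuts collapse on high-uptake
or low-contrast lesions, and gradient tools need manual adjustment.

`mopet` implements an automatic alternative: **multi-level Otsu
thresholding (MO-PET)** restricted to an ellipsoidal volume of interest
(VOI) drawn loosely around the lesion. Given the histogram of in-VOI SUV
values with occupation probabilities $P_i$, the method finds the $K-1$
thresholds $T_1 < \dots < T_{K-1}$ that minimize the probability-weighted
within-class variance

$$\sum_{k=1}^{K} P_k\,\sigma_k^2,\qquad
  \mu_k = \sum_{i \in k} i\,\frac{P_i}{P_k},\qquad
  \sigma_k^2 = \sum_{i \in k} (i-\mu_k)^2\,\frac{P_i}{P_k},$$

(equivalently, maximize the between-class variance) over all ordered
threshold sets, and takes the hottest class — voxels with SUV
$\ge T_{K-1}$, restricted to the connected component of the SUVmax
voxel — as tumor. MTV is the voxel count times the voxel volume in cm³.

The package is aimed at PET quantification researchers: it bundles the
comparator segmentations, a NEMA-IQ-style phantom simulator with known
ground truth so every method can be validated without patient data,
DICOM/NIfTI/RT-Structure-Set I/O, and the agreement panel used to compare
MTV against a reference gross tumor volume (GTV): MTV/GTV ratio, Spearman
correlation, intra-class correlation ICC(A,1) with 95% CI, and
Bland-Altman bias and limits of agreement.

## Worked example

Simulate a 28 mm sphere at lesion-to-background ratio 4, degraded by a
6 mm FWHM point-spread function and 10% noise, then segment it three
ways inside one VOI:

```r
library(mopet)
ph <- generate_phantom(phantom_spec(
  shape = c(64, 64, 64), spacing = c(2, 2, 2), background_suv = 1,
  spheres = data.frame(x = 63, y = 63, z = 63, diameter = 28, lbr = 4),
  psf_fwhm = 6, noise_coef = 0.10, seed = 1))
voi <- ellipsoid_voi(center = c(63, 63, 63), semiaxes = c(24, 24, 24))

res <- segment_mo_pet(ph$image, voi)    # K = 2, 128 bins
res
#> <threshold_set> K = 2, thresholds (SUV): 2.2645
#>   within-class objective: 0.153253 SUV^2
#> <seg_mask> method 'mo-pet': 1486 voxels, 11.89 cm^3
mask_volume(ph$truth[[1]])
#> [1] 11.776
```

The Otsu cut lands at SUV 2.26 — between background (1) and the blurred
lesion plateau (~4) — and recovers 11.89 cm³ against a ground truth of
11.78 cm³ (ratio 1.01). On the same phantom `segment_absolute_suv(, 2.0)`
gives 13.42 cm³ and `segment_percent_suvmax(, 0.30)` 17.53 cm³.

Comparing per-case volumes against a reference GTV:

```r
agreement_report(list("mo-pet" = mtv_mopet, "suv-2.0" = mtv_suv2), gtv)
#>    method  n ratio_mean ratio_sd spearman_rho spearman_p   icc icc_lo icc_hi ba_bias ba_sd ...
#> 1  mo-pet 48       1.10    0.203        0.932   7.30e-22 0.902  0.793  0.950    98.9   200
#> 2 suv-2.0 48       1.01    0.469        0.741   1.76e-09 0.631  0.424  0.775    34.7   506
```

One row per method: mean ± SD of the MTV/GTV ratio (1 = perfect volume
reproduction), Spearman rank correlation with two-sided p, ICC(A,1)
(two-way random effects, absolute agreement, single measures) with its
F-based 95% CI, and the Bland-Altman bias ± SD of differences with 95%
limits of agreement, all in cm³.

Real data come in through `load_pet_suv()` (a DICOM PET series, converted
to body-weight SUV with header-driven decay correction), `read_nifti()`
(volumes already in SUV units), and `read_rtss()` +
`rasterize_contours()` (reference contours to masks).

A command-line front end is installed at `inst/cli/mopet`
(`mopet phantom | segment | agreement | recovery`).

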