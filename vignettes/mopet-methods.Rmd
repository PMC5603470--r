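---
title: "Methods: multi-level Otsu PET segmentation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level Otsu PET segmentation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

All segmentation in `mopet` happens inside a user-drawn ellipsoidal
volume of interest (VOI) on a 3-D PET volume in SUV units. The SUV values
of the in-VOI voxels are discretized into `n_bins` equal-width bins over
their own range; bin occupancies normalized to probabilities $P_i$ form
the intensity histogram. Multi-level Otsu chooses the $K-1$ ordered
thresholds minimizing the probability-weighted within-class variance
$\sum_k P_k \sigma_k^2$, with class means and variances computed over bin
centers. Minimizing within-class variance is equivalent to maximizing
between-class variance because their sum is the fixed total variance.
The tumor mask is the hottest class, $\mathrm{SUV} \ge T_{K-1}$
(inclusive), intersected with the 26-connected component containing the
in-VOI SUVmax voxel.

Assumptions worth stating plainly:

* the VOI contains the whole lesion plus enough background that the
  histogram is at least bimodal;
* uptake classes are separable in intensity — the method knows nothing
  about shape or texture;
* SUV values are non-negative and finite (enforced at construction).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `K` (classes) | 2 | — | see below |
| `n_bins` | 128 | — | resolves lesion/background structure at any clinical SUV range while keeping the threshold search instant; exposed as `--bins` |
| `connected` | `TRUE` | — | a VOI may graze a second hot structure; keeping only the SUVmax voxel's component prevents disjoint hot spots inflating MTV |
| VOI margin (experiments) | 10 | mm | a comfortable manual margin around the lesion; recovery ratios change by < 10% between 5 and 20 mm margins |
| `psf_fwhm` (phantom) | 6 | mm | typical reconstructed clinical PET resolution |
| `noise_coef` (phantom) | 0.10 | — | Gaussian noise with SD proportional to local intensity, a simple stand-in for reconstructed-PET noise |
| absolute cuts | 2.0 / 2.5 / 3.0 | SUV | the conventional clinical values |
| percent cuts | 30 / 40 / 50 / 60 | % SUVmax | the conventional clinical values |

### Why the default is K = 2

The class count was genuinely open: the method is defined for an
arbitrary number of classes, and a three-class reading
(background / spill-over rim / tumor) is attractive on paper. We measured
it. With the tumor defined as the hottest class, K = 3 places the tumor
threshold *above* the partial-volume rim of a blurred sphere and
systematically underestimates volume by 30–40% on 6 mm-FWHM phantoms
(recovered/true ratios 0.59–0.69 across diameters 17–28 mm and
lesion-to-background ratios 4–8), while K = 2 puts the single cut near
the lesion's half-maximum — the volumetrically correct boundary for a
blurred step edge — and recovers 1.00–1.13 of truth under the same
conditions. K = 2 is therefore the default; K remains configurable (2–5)
for lesions with a genuine intermediate class (e.g. necrotic cores), with
the caveat above documented rather than hidden.

## Numerical choices

* **Bins and thresholds.** Bins are left-closed, right-open, the last bin
  right-inclusive. Candidate thresholds are interior bin edges, so a
  threshold "inside" a bin cannot occur by construction; a user-supplied
  threshold that falls inside a bin assigns that bin to the lower class.
* **Solver.** The default solver is an exact dynamic program over prefix
  sums ($O(KB^2)$); an exhaustive enumerator over all
  $\binom{B-1}{K-1}$ cut vectors is kept as a verification path, and the
  two are asserted identical in the test suite. Both break objective ties
  toward the lexicographically smallest threshold vector, making results
  deterministic.
* **Point masses.** A class whose mass lies in a single bin has variance
  exactly 0 (not a prefix-sum rounding residue); this keeps the
  separable-cluster objective exactly zero.
* **Degenerate inputs.** A constant region raises a "degenerate
  distribution" error rather than returning an arbitrary mask; a VOI that
  misses the grid errors; fewer than K occupied bins errors
  ("insufficient distinct levels"). Empty classes report zero moments and
  are flagged.
* **Inclusion rules.** One center-based rule everywhere: a voxel belongs
  to an ellipsoid, sphere, or polygon iff its center does. Thresholds are
  inclusive ($\ge$).
* **Gradient comparator.** `segment_gradient()` is a *generic*
  gradient-shell method (Gaussian smoothing, central-difference gradient
  magnitude, per-ray maximum along ~500 deterministic ray directions from
  the SUVmax voxel) and is labeled `"gradient (generic)"`; it approximates
  the behavior of commercial gradient tools without claiming equivalence
  to any of them.

## Statistics

The agreement panel compares per-case MTV to a reference GTV:

* **Ratio** mean ± sample SD of $\mathrm{MTV}_j/\mathrm{GTV}_j$.
* **Spearman** rho from mid-rank Pearson correlation; two-sided p by the
  $t$ approximation for $n \ge 10$ and the exact permutation distribution
  (all $n!$ permutations) below that.
* **ICC.** No ICC variant was inherited with the problem; we fix
  ICC(A,1) — two-way random effects, absolute agreement, single
  measures — because the hypothesis of interest is that MTV *equals* GTV,
  not merely that they co-vary; a consistency ICC would reward a method
  that is biased by a constant offset. The 95% CI uses the McGraw–Wong
  F-distribution method with Satterthwaite degrees of freedom. The
  implementation is checked against an independent reference to 1e-9 and
  by parameter-recovery simulation (coverage ≥ 90% over 500 replicates).
* **Bland–Altman.** Differences are fixed as MTV − GTV; the inline
  "bias ± value" is the SD of the differences, with the 1.96·SD limits of
  agreement reported separately.

## What the phantom generator does and does not emulate

`generate_phantom()` builds a piecewise-constant volume (warm background,
hot spheres at given diameters and lesion-to-background ratios — the six
NEMA image-quality sphere sizes by default), convolves with an isotropic
Gaussian PSF, and adds intensity-proportional Gaussian noise clamped at
zero. Ground-truth masks come from the unblurred geometry, so recovered
volume can be scored against exact truth.

It emulates the two dominant degradations of reconstructed PET — finite
resolution (partial volume) and intensity-dependent noise. It does **not**
emulate correlated reconstruction noise, non-stationary resolution,
scatter/attenuation artifacts, respiratory motion, irregular or
heterogeneous lesions, or anatomic background structure. A green phantom
test therefore establishes algorithmic correctness and robustness to
blur and voxel noise — not clinical accuracy on patient data, which in
the source setting involved manually drawn VOIs on archive images and an
anatomic (MR-contour) reference volume.

## Known limitations

* K ≥ 3 with the hottest-class rule underestimates blurred compact
  lesions (measured above); the package documents rather than corrects
  this.
* The generic gradient method underestimates small spheres once the blur
  is comparable to the radius (ratio ≈ 0.62 at d = 17 mm, FWHM 6 mm): the
  gradient maximum of a heavily blurred small sphere sits inside the true
  surface. This mirrors the general caution that gradient methods need
  favorable contrast and size.
* DICOM support is deliberately minimal: uncompressed little-endian PET
  series and RT Structure Sets, body-weight SUV only (no lean-body-mass
  or BSA variants), no PET/MR registration — volumes are compared in cm³,
  which the ratio/agreement statistics permit, and a trilinear/nearest
  `resample_image()` is the only resampling concession.
* Phantom spheres must not overlap; lesions are spheres only.
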