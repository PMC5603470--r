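Package: mopet
Title: Multi-Level Otsu PET Tumor Segmentation and Method Agreement
Version: 0.1.0
Authors@R: person("mopet", "maintainers", email = "mopet@example.org",
    role = c("aut", "cre"))
Description: Segmentation of metabolic tumor volume (MTV) on 3-D PET images
    in standardized uptake value (SUV) units. Implements multi-level Otsu
    thresholding (MO-PET) inside an ellipsoidal volume of interest, the
    conventional comparator segmentations (absolute SUV thresholds, fixed
    percentage of SUVmax, and a generic gradient-based delineation), NEMA
    image-quality-style synthetic phantom generation with known ground
    truth, DICOM PET body-weight SUV conversion, NIfTI-1 and RT Structure
    Set I/O, and the agreement statistics used to compare MTV against a
    reference gross tumor volume: MTV/GTV ratio, Spearman correlation,
    intra-class correlation ICC(A,1) with F-based confidence intervals,
    and Bland-Altman analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
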