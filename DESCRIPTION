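Package: aneuseg
Title: Threshold-Based Level-Set Segmentation of Intracranial Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation of intracranial aneurysms from 3D CT-angiography-like
    volumes with a threshold-based level-set (TLS) method: a level-set evolution
    whose speed combines a region threshold term with a geodesic boundary term,
    the intensity threshold being estimated automatically from a Chan-Vese
    pre-segmentation through a Chebyshev confidence-interval relation and refined
    iteratively during the evolution. Includes the two reference segmenters it is
    validated against (region growing with intensity thresholds, Chan-Vese),
    a six-metric validation suite (volume difference, Jaccard overlap, false
    positive/negative ratios, Hausdorff and mean absolute surface distance),
    readers and writers for NIfTI, NRRD and MetaImage containers, and a
    synthetic vessel-plus-aneurysm phantom generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
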