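Package: isodiff
Title: Isodose Surface Difference Analysis for Radiotherapy Dose Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two three-dimensional radiotherapy dose distributions by
    the shape of their isodose surfaces. Each isodose surface is parametrized
    as a histogram of point distances from the plan isocenter, histogram pairs
    are scored with the Bray-Curtis dissimilarity, and per-isodose deviations
    are normalized against plan-specific tolerance limits derived from the
    +/- 1 mm multileaf-collimator QA criterion mapped through the local dose
    gradient. Includes DICOM RTDOSE and plain-text dose-grid readers, a
    synthetic plan generator with analytically known isodose geometry, a
    rotation pre-flight check, a global gamma-index baseline, and chart and
    report export for patient-specific QA workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
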