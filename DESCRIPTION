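Package: mrseries
Title: Hierarchical Classification of MRI Series from DICOM Metadata and Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic labelling of magnetic-resonance imaging series from
    DICOM header metadata and a single representative slice. A cascade of five
    conditionally connected classifiers assigns each series a composite label
    (Others / Weighting / Fat Suppression / Contrast / Family): four
    tree-ensemble modules operate on encoded DICOM tags while the contrast
    module analyses the central slice of a representative volume with a small
    convolutional network. Includes a synthetic multi-vendor DICOM cohort
    generator with label-conditional header rules and body phantoms, a minimal
    explicit-VR little-endian DICOM reader/writer, patient-grouped splitting
    and cross-validation, and confusion-matrix metrics with bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
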