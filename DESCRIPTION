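Package: rbcprofiler
Title: Single-Cell Morphological Profiling of Red Blood Cells in Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for interpretable single red blood cell
    analysis in paired brightfield/fluorescent microscopy fields: instance
    segmentation behind a pluggable backend contract, detection and erasure of
    intracellular Ca2+-loaded vesicles in the fluorescent (Fluo-4) channel,
    extraction of a fixed 135-feature catalog (shape, intensity and
    gray-level-matrix texture statistics per channel plus vesicle counts),
    annotation sampling, and automated training of interpretable tree
    classifiers with grouped cross-validation and normalized feature
    importances. Includes a synthetic field generator with full ground truth
    and evaluation utilities (mask average precision, point matching).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    rpart,
    ranger,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
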