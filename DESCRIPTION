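Package: oviMSI
Title: MALDI Mass Spectrometry Imaging Analysis of Diet Effects on the
    Oviductal Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for MALDI mass spectrometry
    imaging (MSI) of the mouse oviductal epithelium under an obesogenic
    diet: continuous-mode imzML input/output, morphological (Tophat)
    baseline correction, total-ion-count normalization, low-mass
    deflection and matrix-cluster exclusion windows, orthogonal matching
    pursuit peak detection with centroid alignment, spatial segmentation
    by bisecting k-means under the Manhattan metric, region-of-interest
    selection against a reference mask, bidirectional ROC detection of
    diet-discriminative m/z features, and putative phospholipid
    annotation from a formula-derived monoisotopic mass table. Includes
    a synthetic ion-image study generator with planted ground truth so
    every stage can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
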