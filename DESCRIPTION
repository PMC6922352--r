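Package: picasso
Title: Distal Airway Segmentation from Chest CT by Graph Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments the bronchial tree from chest CT volumes with the
    PICASSO strategy: appearance maps built from a bank of oriented cropped
    anisotropic Laplacian-of-Gaussian tubular filters, a multiresolution
    max-pooling scheme so one small kernel detects bronchi of every caliber,
    per-scan and per-branch binarization thresholds optimized by bisection on
    a graph-theoretic complexity statistic of the segmentation skeleton, and
    leakage removal by pruning graph cycles followed by inverse
    skeletonization. Includes a synthetic bronchial-tree phantom generator
    with ground-truth centerlines, radii and injected leakage, plus
    EXACT09-style evaluation metrics, so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
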