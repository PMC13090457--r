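Package: embolimetry
Title: MicroCT Quantification of Particulate Embolic Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the spatial distribution of radiopaque embolic
    microspheres in volumetric microCT images of whole organs. Builds
    depth-stratified cortical shell masks by Euclidean surface erosion,
    segments and counts embolic particles, computes volume-normalized
    embolization efficiency and percent embolized cortex, and compares
    paired injection regimes (continuous vs pulsed) with exact Wilcoxon
    signed-rank and paired t tests. Includes a synthetic ellipsoid kidney
    phantom generator with retained ground truth for end-to-end validation
    of the pipeline, plus minimal NIfTI-1 and multi-page TIFF volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
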