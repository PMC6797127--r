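Package: acetquant
Title: Quantitative Assessment of Acetabular Bone Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acetabular bone defects from paired defect/native
    hemipelvis surface models. Computes per-sector bone volume loss and new
    bone formation by voxel-based mesh Boolean operations in four
    periacetabular sectors (cranial roof, anterior column, posterior column,
    medial wall), plus acetabular ovality, lateral center-edge angle,
    implant migration from a least-squares sphere fit, and rim wall-defect
    flags. Cases are assigned to one of 17 defect groups by thresholding
    relative sector loss, with an optional Paprosky correspondence. Includes
    a parametric hemipelvis phantom generator with exact ground truth for
    validation, and cohort-level descriptive and nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
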