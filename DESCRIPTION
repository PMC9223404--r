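Package: epimech
Title: Image-Based Estimation of Epithelial Junction Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating mechanical parameters of epithelial
    tissues from segmented cell geometry. Candidate junction-tension and
    cell-pressure model functions are substituted into quasi-static
    force-balance equations at cell vertices, parameters are fitted by
    (constrained) least squares with a fixed tension scale, and competing
    models are compared by the Akaike information criterion. A cell vertex
    model simulator generates synthetic equilibrium tissues with known
    ground-truth parameters so estimation accuracy, model selection, and
    robustness to segmentation noise can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
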