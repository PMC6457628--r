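Package: plsdecode
Title: Two-Step Partial Least Squares Decoding of fMRI Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-voxel pattern analysis of task fMRI with a two-step partial
    least squares framework: NIPALS partial least squares regression (PLSR) and
    soft-threshold sparse PLSR (SPLSR) for voxel selection, followed by a PLSR
    argmax classifier, alongside a GLM t-map selector and a linear support
    vector machine comparator with one-vs-one voting. Includes a block-design
    BOLD simulator (canonical double-gamma haemodynamic response, Rician noise
    at controlled contrast-to-noise ratio, optional rigid motion), group-level
    pattern maps with cluster-size thresholding, and an evaluation harness that
    runs the full selector-by-classifier factorial with Wilcoxon signed-rank
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
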