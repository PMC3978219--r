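Package: petsuvr
Title: Cortical Amyloid-PET SUVr Quantification in Template and Subject Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two end-to-end quantification pipelines for cortical amyloid
    (AV-45) PET: a template-space route that registers PET onto a tracer
    template and applies a population grey-matter mask, and a subject-space
    route that quantifies on the individual T1 grid with a subject-specific
    grey-matter segmentation and an inverse-warped parcellation atlas. Ships
    a 12-degree-of-freedom affine intensity registration engine, grey-matter
    masking and region-scheme tooling, cerebellum-normalised SUVr tables,
    cohort statistics (paired and two-sample comparisons with Holm
    correction, pooled-SD Cohen's d, empirical ROC with Youden cut-off,
    signal-detection d-prime and bias C), and a digital brain phantom
    generator with known tissue maps, uptake ratios and inter-modality
    misalignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    oro.nifti,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
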