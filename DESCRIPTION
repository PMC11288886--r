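Package: medmtl
Title: Multi-Task Pretraining for Biomedical Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gradient-accumulation multi-task training framework for
    biomedical imaging. One set of shared network blocks (a multi-scale
    encoder, a pixel-dense U-Net-style decoder and a feature-pyramid
    decoder) is trained jointly on heterogeneous tasks - multiclass and
    multilabel classification, semantic segmentation, anchor-free object
    detection with centerness, and multiple-instance classification of
    tomographic slices - with per-task-type loss normalization so that no
    label type dominates the shared representation. Includes
    modality-aware intensity normalization, a patch cache with
    augment-on-retrieval, a frozen/fine-tuning downstream evaluation
    harness with nested data-fraction splits and paired t-tests, and a
    deterministic synthetic geometric-shapes task generator so the whole
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    pROC,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
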