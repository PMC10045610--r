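Package: deformnas
Title: Deformable Convolution and NAS-Searched Feature Pyramid Detection
    for MRI Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale two-stage detector for bright lesions (bone marrow
    oedema) in grayscale MRI-like images. Provides reference implementations
    of bilinear-kernel sampling, deformable convolution and deformable RoI
    average pooling; a feature-pyramid neck assembled from six information
    paths (top-down, bottom-up, scale-balanced, two-step fuse-split, null and
    skip) over a fully connected DAG supernet; single-path one-shot supernet
    training with uniform subnet sampling; an evolutionary search over subnet
    codes ranked by validation AP50; a seeded synthetic-data generator that
    writes PNG images with MS COCO JSON annotations; and COCO-style AP50,
    recall and F1 evaluation. Training runs through a small tape-based
    reverse-mode differentiation engine with compiled kernels, so the whole
    pipeline is testable on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
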