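Package: adaptseg
Title: Adaptive Two-Stage Segmentation of Small Lesions in 3D Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: CPU-oriented coarse-to-fine segmentation of small, sparse lesions
    (lung nodules, brain metastases) in volumetric medical images. A light
    fully-convolutional first stage scores an 8x-downsampled grid to localize
    candidate regions; a heavier decoder then segments only the proposed
    bounding boxes at original resolution, so inference touches a small
    fraction of the volume. Includes NIfTI/MetaImage volume I/O with standard
    CT preprocessing, a synthetic lesion-phantom generator for fully
    self-contained experiments, the two-phase training protocol (weighted
    cross-entropy localization, Dice-loss refinement with a frozen first
    stage), memory-bounded tiled inference, and object-wise evaluation
    (per-object Dice, FROC analysis with average recall).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
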