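Package: sbfseg
Title: Organelle Segmentation and Single-Cell Extraction for Serial
    Block-Face Electron Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for serial block-face (SBF)
    volumes acquired by focused ion beam scanning electron microscopy
    (FIB-SEM) of unicellular algae.  Provides multipage-TIFF volume input
    and output with voxel-spacing metadata, anisotropy correction and
    bilateral denoising, a slice-wise ("scanning") attention U-Net trained
    with the Tversky loss for six-class organelle segmentation, fusion of
    predictions inferred along all three volume axes, per-class
    intersection-over-union scoring with stage-stratified cross-validation
    bookkeeping, and extraction of individual cells from multi-cell scenes
    by foreground masking and seeded three-dimensional watershed.  A
    phantom generator produces synthetic dividing-cell volumes with ground
    truth labels across five division stages so that the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
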