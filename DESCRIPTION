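Package: nucleiseg
Title: Light-Weight Dense-Encoder U-Net Segmentation of Microscopy Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end semantic segmentation of cell nuclei in bright- and
    dark-field microscopy images with a light-weight, densely connected
    encoder U-Net ("U-Net+"), alongside reference U-Net and nested U-Net
    (U-Net++) builders under identical block conventions. Provides a
    synthetic nuclei image generator with instance ground truth, readers and
    writers for the Kaggle Data Science Bowl 2018 stage-1 dataset layout
    including column-major run-length mask encoding, a CLAHE plus
    total-variation preprocessing front end, 256x256 grid/random patch
    extraction with photometric and geometric augmentation, a from-scratch
    CPU training engine (negative-log-Dice plus binary cross-entropy loss,
    Adam, best-validation checkpointing), tiled whole-image inference with
    overlap-max fusion and morphological cleanup, and per-cell IOU matching
    with AP50:95-style precision evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
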