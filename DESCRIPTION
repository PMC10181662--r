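Package: seedHSI
Title: Processing and Deep-Learning Classification of Hyperspectral Seed Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for hyperspectral imaging of crop seeds grown under
    temperature stress: reading and writing hypercubes (ENVI and HDF5),
    white/dark reflectance calibration (Shafer model), seed segmentation from
    panel images, ellipse-based shape and spectral phenotype descriptors,
    seed-level classification with a 3-D convolutional neural network,
    pixel-level spectral classification with a deep fully-connected network,
    evaluation metrics (overall/average accuracy, Cohen's kappa, per-class
    precision/recall/F1), classification maps, PCA plus t-SNE embeddings, and
    a synthetic panel generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    rhdf5,
    Rtsne,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
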