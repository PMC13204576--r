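Package: strokegraph
Title: Superpixel-Graph Chebyshev Convolutional Networks for Ischemic
    Stroke Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments ischemic stroke lesions in CT perfusion slices by
    converting each slice into a superpixel region-adjacency graph (SLIC
    partition, Gaussian-weighted edges, intensity-histogram node features)
    and classifying nodes with a five-block Chebyshev spectral graph
    convolutional network trained with Adadelta and cross-entropy.
    Includes Hounsfield-window preprocessing with training-set
    augmentation, a seeded synthetic brain-phantom cohort generator,
    patient-level k-fold cross-validation, segmentation metrics (Dice,
    Jaccard, sensitivity, precision, accuracy, ROC), and an SNR-controlled
    additive-white-Gaussian-noise robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pROC,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
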