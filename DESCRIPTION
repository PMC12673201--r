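Package: stenonet
Title: Gaussian Center-Weighted 3D CNN for Coronary MRA Stenosis Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 21x21x21-voxel coronary magnetic resonance angiography
    (CMRA) patches as containing or not containing significant (>=50% diameter
    reduction) stenosis. Implements a two-block 3D convolutional network with a
    fixed Gaussian center-weighting layer between the blocks, weighted
    cross-entropy training with SGD-momentum and early stopping, patient-level
    stenosis-balanced four-fold cross-validation, and ROC evaluation with the
    Youden operating point and the DeLong test for correlated AUCs. A synthetic
    vessel-phantom generator produces CMRA-like volumes and annotation tables so
    the whole pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
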