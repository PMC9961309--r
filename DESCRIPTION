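Package: mgmtfuse
Title: Hybrid Radiomic and CNN Latent Feature Fusion for MGMT Promoter
    Methylation Classification from Brain MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage radiogenomic classification pipeline for predicting
    MGMT promoter methylation status (MGMT+/MGMT-) from 2-D grayscale brain
    MRI slices. Stage one trains a small convolutional neural network and
    harvests the activations of its two hidden fully connected layers as
    latent features; stage two extracts hand-crafted texture descriptors
    (13 direction-averaged Haralick features from gray-level co-occurrence
    matrices, a histogram of oriented gradients, and uniform local binary
    patterns). The two stages are fused into a 684-dimensional hybrid
    feature vector, min-max normalised, and classified with k-nearest
    neighbours or support vector machines under stratified 10-fold
    cross-validation with a full suite of performance measures (accuracy,
    sensitivity, specificity, precision, NPV, F1, MCC, AUC). Includes a
    blank-slice rejection filter, a deterministic two-class texture phantom
    generator for fully synthetic end-to-end testing, and feature-table
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jpeg,
    jsonlite,
    png,
    RNifti,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
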