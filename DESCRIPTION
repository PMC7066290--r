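Package: mprad
Title: Multiparametric Radiomics for Co-Registered Imaging Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Texture analysis of multiparametric radiological images
    (e.g. multiparametric MRI) built on per-voxel tissue signatures: the
    vector of intensities one voxel takes across all co-registered
    channels. Provides five feature families computed jointly over all
    channels rather than per image: the tissue signature probability
    matrix (joint entropy, uniformity, multivariate mutual information),
    pooled first-order histogram statistics, a cross-voxel tissue
    signature co-occurrence matrix with the twenty-two Haralick-type
    features, per-voxel complex-interaction statistics with their
    within-signature relationship matrix, and sliding-window radiomic
    feature maps. Includes an Isomap plus class-cost-weighted linear SVM
    classifier with leave-one-out cross-validated grid search over
    imbalance penalties, ROC/AUC diagnostics, seedable synthetic
    multiparametric phantoms for validation, and NIfTI/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    pROC,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
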