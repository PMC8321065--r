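Package: fmrifusion
Title: Multimodal Functional Connectome Classification for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for diagnosing neurodevelopmental
    conditions from resting-state fMRI. Two connectomic representations are
    built from a 4D BOLD volume and a parcellation atlas: a voxel-by-region
    connectivity fingerprint (Pearson correlation between every voxel time
    series and every region-mean time series) and an upper-triangle
    region-by-region correlation vector. The fingerprint feeds a 3D
    ResNet-18 encoder, the vector a multilayer perceptron; their feature
    vectors are concatenated and classified by a fully-connected fusion
    head trained in two phases (independent encoder training, then
    end-to-end fine-tuning). Includes a synthetic-cohort simulator with
    group-structured latent covariance, Grad-CAM volume saliency for
    visual explanation of predictions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    MASS,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
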