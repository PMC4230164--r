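Package: searchlightr
Title: Searchlight Multi-Voxel Pattern Analysis for Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for roaming-searchlight
    multi-voxel pattern analysis (MVPA) of block-design fMRI: a synthetic
    two-group cohort simulator with known informative regions, voxelwise GLM
    estimation with canonical double-gamma HRF regressors, discrete-cosine
    high-pass filtering and Gaussian smoothing, spherical-searchlight linear
    support-vector decoding with leave-one-run-out cross-validation,
    permutation-based voxel- and cluster-level group inference, and a
    mass-univariate comparison arm that quantifies the sensitivity advantage
    of multivariate decoding for mean-amplitude-matched group differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
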