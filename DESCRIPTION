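Package: crossdecode
Title: Cross-Task Multivoxel Pattern Decoding for Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying preparatory attentional templates with
    cross-task multivoxel pattern analysis (MVPA). Provides generators for
    cued visual-search, 1-back and localizer task designs, a forward
    simulator of multivoxel BOLD data with known condition patterns,
    canonical-HRF design matrices and voxelwise GLM estimation, ROI and
    searchlight cross-classification with pairwise linear support vector
    machines, permutation-based group inference with Bonferroni control,
    threshold-free cluster enhancement (TFCE) for whole-brain maps, and
    power analysis for paired-difference designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
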