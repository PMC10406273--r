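Package: spatiodyn
Title: Voxel-Wise Spatiotemporal Brain-Network Dynamics from 4D fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes resting-state fMRI at the level of 5D spatiotemporal
    brain networks: a residual encoder/decoder 3D convolutional regressor turns
    each fMRI timepoint into per-network voxel-wise score maps, and downstream
    statistics summarize them as time-mean and temporal-deviation maps,
    voxel-wise two-sample t-maps, static and sliding-window dynamic functional
    network connectivity, k-means connectivity states and per-subject state
    occupancy ratios. Includes a seeded synthetic-study generator with known
    overlapping networks, domain-structured temporal coupling, voxel-level
    spatial dynamics and injectable group effects, so every stage can be tested
    end-to-end with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
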