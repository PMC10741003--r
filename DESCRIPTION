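Package: mcgss
Title: State-Space Estimation of Myocardial Current Densities from
    Magnetocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs myocardial current densities from magnetocardiographic
    (MCG) sensor array measurements with a nested state-space algorithm. A
    voxelized electrophysiological model of the heart propagates activation
    between neighboring voxels through first-order Thiran all-pass filters; a
    sparse Kalman filter estimates the per-voxel current densities given the
    measurements; and an outer gradient-descent loop refines the model's gain
    and delay parameters. Includes the Biot-Savart lead-field forward model, a
    minimum-norm pseudoinverse baseline, a one-layer simulated heart sheet for
    validation, and threshold segmentation of the resulting activity maps into
    healthy and pathological tissue with DICE scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
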