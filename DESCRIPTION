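Package: stenoflow
Title: Turbulence Inlet Boundary-Condition Sensitivity of Post-Stenotic RANS Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady incompressible finite-volume RANS solver (SIMPLE with the
    standard k-epsilon closure and wall functions) on body-fitted structured
    meshes of a parametric stenosis channel, together with tooling to study
    how turbulence inlet boundary conditions affect post-stenotic flow
    accuracy: exact mapping of velocity and turbulent kinetic energy profiles
    from a full-model ground truth onto truncated sub-models, arbitrary
    turbulence-intensity inlets, a synthetic 4D-flow-MRI-like measurement
    emulator (voxel averaging plus Gaussian noise at controlled SNR), mean
    absolute error metrics over a region of interest, and an experiment
    pipeline orchestrating the full study matrix from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
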