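Package: rhinoflow
Title: Nasal Airflow Simulation and Cohort Analysis for Turbinate Surgery Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis of nasal airflow before and after inferior
    turbinate reduction surgery. Generates synthetic cone-beam CT style nasal
    phantoms with ground truth, segments the airway by Hounsfield-unit
    thresholding with isolated-region removal, solves steady laminar
    incompressible flow with conjugate mucosal heat transfer (Robin wall
    condition) on a voxel-native staggered finite-volume grid, integrates wall
    shear force, heat transfer and pressure loss over anatomically defined
    regions of the inferior turbinates, and runs the paired nonparametric
    cohort statistics (Wilcoxon signed-rank, Spearman rank correlation) used
    in pre/post surgical studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
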