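Package: fcmech
Title: Mechanism Mapping of Resting-State Functional Connectivity Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of resting-state network functional
    connectivity in two-group neuroimaging cohorts. Implements temporally
    concatenated group spatial independent component analysis with automatic
    model-order selection by the Laplace approximation to the probabilistic
    principal component evidence, dual regression back-projection of group
    maps to single subjects, voxelwise general linear model inference with
    Freedman-Lane permutation testing, threshold-free cluster enhancement
    and max-statistic family-wise error correction, a global functional
    connectivity (gFC) index for ranking network alterations, a sequential
    masked correlation cascade against lesion load and clinical severity
    covariates, and a voxelwise classifier that assigns mechanism scenarios
    (lesion-driven reduction, true/false/attempted compensation,
    neurodegeneration, pre-symptomatic damage) from the sign pattern of the
    cascade statistics. A synthetic-cohort generator with planted ground
    truth makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
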