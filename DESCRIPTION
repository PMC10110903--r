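Package: desep
Title: Deep-Learning Segmentation Based Prognostication for Lung SBRT Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a deep-learning segmentation based prognostication
    (DESEP) pipeline for non-small cell lung cancer treated with stereotactic
    body radiotherapy: a 3D segmentation U-Net whose central latent vector
    supplies unsupervised radiomic features, k-medoids clustering with
    Silhouette-based cluster-count selection and LASSO retention of
    outcome-associated medoid features, logistic prognosticators for
    two-year overall, disease-specific and local progression-free survival,
    RECIST v1.1 response categorization engines (manual unidimensional,
    computer-based unidimensional from auto-segmentation, and volumetric
    with ellipsoid or spherical thresholds), and from-scratch censored
    survival statistics (Kaplan-Meier, log-rank, binary-covariate Cox hazard
    ratios, Harrell's c, Cramer's phi). A synthetic tumor-phantom module
    generates 3D image cohorts with ground-truth masks, serial follow-up
    trajectories and censored outcomes carrying a planted morphology signal,
    so the entire pipeline is exercisable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    glmnet,
    parallel,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
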