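Package: GraphSEM
Title: Graph-Specified Structural Equation Modeling for Multi-Omics Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Declare mechanistic hypotheses as graphs over multi-omics
    variables (expression, somatic mutations, thresholded copy number,
    clinical covariates, overall survival) and latent factors, and test them
    by structural equation modeling. The engine compiles a model graph to the
    RAM (reticular action model) matrix form, fits it by normal-theory maximum
    likelihood, and reports per-link estimates, standard errors, z-scores and
    global fit indices (TLI, CFI, RMSEA, SRMR). Edges into right-censored
    survival endpoints are estimated by Cox proportional-hazards regression
    with latent parents represented by regression-method factor scores, so
    that mediation and confounder adjustment behave as in multivariable
    survival models. Also provides direct/indirect/total effect decomposition,
    Kaplan-Meier stratification, an all-against-all association screen with
    Benjamini-Hochberg FDR control and a precompute/query store, co-occurrence
    tables for binary genomic alterations, clustered-heatmap ordering, readers
    for expression/MAF/GISTIC/clinical files, and a synthetic cohort simulator
    drawn from a known ground-truth structural model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
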