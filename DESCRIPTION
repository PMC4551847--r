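Package: lmmspline
Title: Linear Mixed Model Splines for Time-Course Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-stage framework for analysing time-course omics
    experiments (transcriptomics, proteomics): noise-based profile
    filtering using variance-ratio statistics and two-component
    model-based classification; per-molecule modelling with penalized
    truncated-line-basis splines whose coefficients are random effects,
    selected serially among four nested mixed models by likelihood ratio
    tests, with derivative (rate-of-change) profiles; and downstream
    analysis by trajectory-level differential expression testing (time,
    group and group-by-time effects with Benjamini-Hochberg FDR control)
    and by clustering of modelled trajectories with Dunn-index selection
    of algorithm and cluster number plus hypergeometric set enrichment.
    Includes a simulation module that generates benchmark datasets and
    scores differential-expression calls by sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    cluster,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
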