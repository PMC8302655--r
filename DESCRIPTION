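Package: bmsr
Title: Bayesian Multi-Source Regression for Cross-Study Drug-Response
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint sparse Bayesian regression of drug response on gene
    expression across multiple studies (BMSR), and its multi-task extension
    across drug panels (BMSMTR), using a Finnish (regularized) horseshoe
    prior sampled by a No-U-Turn Hamiltonian Monte Carlo sampler.  Includes
    ex vivo drug-screen processing (3- and 4-parameter log-logistic
    dose-response fitting, normalized area-under-curve, quality-control
    filters), the general-response-across-drugs (GRD) statistic and its
    use as a covariate in cross-study prediction, Stouffer-combined
    biomarker prioritization, single-sample gene-set enrichment (GSVA-style)
    scoring with a built-in eight-gene monocytic signature, ridge-regression
    baselines, and synthetic-data generators that emulate the statistical
    structure of multi-study pharmacogenomic screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
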