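Package: mtmegp
Title: Multi-Trait Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic-enabled prediction of multiple correlated plant traits
    measured across several environments. Implements a Bayesian multi-trait
    multi-environment mixed model (a matrix-variate generalisation of GBLUP)
    fitted by Gibbs sampling with Kronecker-structured covariances, a
    multi-output densely connected neural network with dropout regularisation
    and grid-search hyperparameter tuning, marker quality control with a
    VanRaden-style genomic relationship matrix, cell-level (CV2)
    cross-validation with heritability-adjusted Pearson accuracy, and a
    simulator that generates phenotypes from the mixed model's own generative
    process so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
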