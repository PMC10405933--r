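Package: enviroGS
Title: Environmental Covariate Selection for Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based Bayesian genomic prediction for multi-environment
    trials with optional enviromic (environmental covariate) information.
    Implements genomic, environmental and Hadamard-product interaction
    relationship matrices, a Gibbs sampler for Gaussian kernel mixed models,
    two leakage-safe covariate selection procedures (a descending Pearson
    correlation threshold ladder and a Boruta-style shadow-feature random
    forest selector), engineered covariate blocks (sign-aligned averages and
    quadratic augmentation), a registry of fifteen predictor configurations,
    and leave-one-environment-out benchmarking with normalized RMSE,
    correlation, calibration regression, relative efficiency and win-count
    summaries. A synthetic multi-environment trial generator with known
    ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
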