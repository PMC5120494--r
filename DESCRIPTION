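Package: rcgmeth
Title: Ratio-of-Correlated-Gammas Regression for DNA Methylation Beta Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Likelihood-based regression for DNA methylation beta values
    built on the Wicksell-Kibble bivariate gamma distribution for the
    methylated and unmethylated signal intensities. Models the beta value
    as the ratio of two positively correlated gamma variables with common
    shape, links the mean-intensity ratio to covariates through a
    log-linear predictor, and provides maximum-likelihood fitting with
    Wald-type downstream tests. Includes self-contained beta regression
    and M-value regression comparators, predictive log-score model
    comparison, samplers for the Kibble distribution, the ratio density
    and a Gumbel-copula construction, a power/type-I-error simulation
    harness, and a site-wise EWAS pipeline with BH/BY false discovery
    rate control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
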