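Package: dfbayes
Title: Distribution-Free Bayesian Inference for Binary, Rank and Ordinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian counterparts to the classical nonparametric toolbox,
    built on beta-Bernoulli conjugacy. Provides beta-distribution
    descriptives with highest-density intervals, binomial updating,
    interval and point (Savage-Dickey) Bayes factors, Monte Carlo
    inference for linear contrasts of independent binomial rates,
    Bayesian McNemar, sign and median tests, discrete-grid posteriors
    for the Wilcoxon signed-rank phi_w and Mann-Whitney Omega_E
    parameters with a large-sample beta approximation, power simulators
    comparing the distribution-free tests against the t test under nine
    data-generating models, and rank-based bivariate association
    (Kendall tau-A with full tie corrections, the concordance
    proportion phi_c, a free-parameter-adjusted goodness-of-fit
    concordance, and Goodman-Kruskal gamma for ordered contingency
    tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
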