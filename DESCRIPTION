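Package: skewsim
Title: Monte Carlo Comparison of the Welch t and Wilcoxon-Mann-Whitney
    Tests on Skewed Distributions
Version: 1.0.0
Authors@R:
    person("Skewsim", "Maintainers", email = "maintainers@skewsim.org",
           role = c("aut", "cre"))
Description: Tools to study the behaviour of the Welch unequal-variance
    t-test and the Wilcoxon-Mann-Whitney (WMW) rank-sum test when the two
    sampled distributions are skewed, have exactly equal means, and differ
    only in spread. Constructs pairs of gamma or lognormal distributions
    matched on mean and coefficient of skewness with a prescribed
    standard-deviation ratio, computes the stochastic-superiority
    probability P(X < Y) by adaptive quadrature, and runs reproducible
    Monte Carlo simulations of rejection rates and p-value comparisons
    over a scenario grid, with aggregation helpers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
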