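Package: growthdesign
Title: Optimal Test Design for Estimating Mean and Percentile Ability Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing pairs of achievement test forms linked by anchor
    items so that a population's ability growth between two administrations is
    estimated with minimal asymptotic variance under the two-parameter logistic
    item response model. Continuous difficulty configurations are found with a
    particle swarm minimizer over weighted-sum test-information criteria built
    from discretized ability distributions (including prior-integrated
    optimum-in-average weights); discrete test assembly from a calibrated item
    pool uses simulated annealing with greedy refinement and an exhaustive
    oracle for small pools. Includes study harnesses for design sweeps,
    solution-stability analysis, robustness of optimum-in-average designs, and
    Monte-Carlo validation of the asymptotic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
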