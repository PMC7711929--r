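Package: ingarchmonitor
Title: Robust Online Monitoring of Parameter Change in INGARCH Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Online (closed-end) monitoring of parameter change in
    integer-valued GARCH(1,1) models whose conditional distribution belongs
    to a one-parameter exponential family (Poisson, negative binomial).
    Provides minimum density power divergence estimation (MDPDE, including
    the MLE as the alpha = 0 special case), score-based CUSUM monitoring
    statistics with analytic, Monte Carlo and parametric (warp-speed)
    bootstrap control limits, a scenario simulator with parameter changes
    and Bernoulli-Poisson outlier contamination, and a size/power study
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
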