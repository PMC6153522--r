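Package: paneltrend
Title: Trend Estimation for Spatially Balanced Panel Survey Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and testing long-term trend from complex,
    spatially balanced panel surveys of discrete natural resources such as
    mountain lakes. Implements the unweighted linear mixed trend model with
    random year effects and correlated random site intercepts and slopes
    (REML with Satterthwaite degrees of freedom), simple and weighted linear
    regression on design-based annual status estimates (Horvitz-Thompson
    means with the local-neighborhood variance estimator), and
    probability-weighted iterative generalized least squares (PWIGLS) with a
    linearization variance estimator. Includes a synthetic finite-population
    generator emulating a mountain-lake sampling frame, a spatially balanced
    (GRTS-style) sample-draw algorithm with equiprobable, stratified, and
    unequal-probability designs, McDonald-notation revisit-design machinery,
    and a Monte Carlo engine summarizing relative bias, confidence-interval
    coverage, test size, and power across design scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
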