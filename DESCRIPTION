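Package: heatmort
Title: Heat Stress and Heat-Attributable Mortality Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for projecting heat stress and
    heat-attributable mortality over gridded scenario climate. Computes a
    piecewise heat stress index (HSI) from daily temperature and relative
    humidity (Rothfusz regression with the Steadman simple-formula branch
    and low/high-humidity adjustments), fits site-level distributed lag
    nonlinear models (DLNM) to daily mortality counts with quasi-Poisson
    regression, pools site curves to regional exposure-response curves by
    multivariate random-effects meta-analysis (REML) with best linear
    unbiased prediction, projects attributable deaths and rates over
    gridded climate and population, propagates exposure-response and
    inter-model uncertainty by Monte Carlo simulation, and decomposes
    temperature versus humidity contributions with random-forest Gini
    importance. Includes a synthetic-data generator emulating the
    statistical structure of the gridded climate, population, and
    surveillance-site mortality inputs so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite,
    rlang,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
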