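Package: asriskmap
Title: Spatial Mapping of Groundwater Arsenic and Associated Health Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatial mapping of groundwater arsenic concentrations
    and the associated human health risk. Implements empirical semivariogram
    estimation with spherical, exponential and Gaussian model fitting,
    ordinary kriging prediction over regular grids, and a from-scratch
    feed-forward neural network regressor trained with the
    Levenberg-Marquardt algorithm, together with concentration-ordered
    k-fold cross-validation for comparing the two interpolators. Winning
    concentration surfaces are converted into USEPA carcinogenic target
    risk (TR) and non-carcinogenic hazard quotient (HQ) layers and
    irrigation/aquaculture suitability zones. A synthetic-data module
    simulates spatially correlated, log-normal, left-censored well datasets
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
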