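Package: roosthab
Title: Presence-Only Roosting-Habitat Modelling with Information-Theoretic
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for landscape-scale presence-only habitat modelling of
    forest bat roosts. Derives terrain predictors (slope, aspect components,
    curvature, D8 ridge extraction, Euclidean distance layers) from a digital
    elevation model, fits maximum-entropy presence-only models with linear and
    quadratic features by L1-regularized convex optimisation, ranks a balanced
    candidate-model set by small-sample-corrected AIC, computes Akaike weights
    and weight-sum variable importances, and produces AICc-weighted
    model-averaged suitability maps classified into suitable and optimal
    habitat. Includes a synthetic ridge-valley landscape generator with a known
    maximum-entropy truth so the whole pipeline can be exercised and validated
    without proprietary spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
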