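Package: rsmopt
Title: Response-Surface and Neural-Network Modelling of Multi-Response
    Extraction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and optimizing designed extraction
    experiments: Box-Behnken designs with coded/natural variable
    transforms, coded second-order polynomial response-surface models
    with per-term ANOVA contribution decomposition and significance-based
    model reduction, feed-forward multilayer-perceptron surrogates
    trained by quasi-Newton minimization, model-adequacy metrics
    (R-squared, RMSE, absolute average deviation), Derringer desirability
    multi-response optimization with coefficient-of-variation validation,
    and chemometric analysis of extract panels (Pearson correlations,
    principal components, NIPALS partial least squares with VIP scores,
    principal-component regression, hierarchical clustering). Ships the
    27-run coffee-husk phenolic extraction dataset used throughout the
    documentation, and a synthetic Box-Behnken generator with known
    ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
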