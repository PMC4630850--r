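Package: predvote
Title: Consensus Voting and Benchmarking of Missense Pathogenicity Predictors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes the categorical outputs of in silico missense-variant
    pathogenicity predictors into a common damaging/tolerated vocabulary,
    forms majority-vote consensus calls over every combination of tools
    (ties called damaging), and scores single tools, tool committees and
    metaservers against functionally characterised truth labels with a
    confusion-matrix battery: accuracy, sensitivity, specificity, the
    Matthews correlation coefficient, ROC curves with DeLong confidence
    intervals for the area under the curve, inter-tool phi association and
    Kruskal-Wallis comparison of accuracies. Evaluation is stratified per
    gene, pooled, and per protein region. A seeded generator of correlated
    synthetic predictor panels (Gaussian-copula latent-difficulty model)
    reproduces the statistical structure of long QT syndrome benchmark
    panels, so the whole pipeline is testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
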