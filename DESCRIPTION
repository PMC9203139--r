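Package: metaboConsensus
Title: Consensus Machine-Learning Prioritization of Metabolites Linked
    with Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks plasma metabolites by the strength and consistency of
    their association with a binary clinical outcome (28-day mortality in
    sepsis) using an ensemble of classification model families. Provides
    limit-of-detection filtering and imputation, log10 preprocessing,
    repeated stratified cross-validation tuned under the precision-recall
    curve, per-family innate feature-importance extraction (penalized
    regression coefficients, PLS-DA VIP scores, shrunken centroid
    differences, tree importances, feature-subset support), and an
    ensemble importance score equal to the fraction of model families
    that select or rank a metabolite highly. Includes a synthetic cohort
    generator with planted effects for end-to-end validation, and
    descriptive cohort statistics (Wilcoxon rank-sum, likelihood-ratio
    chi-squared, PCA variance profiling, hierarchical clustering order).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    e1071,
    mixOmics,
    rpart,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
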