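Package: cohortmgm
Title: Mixed Graphical Model Networks for Cohort Outcome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and analysis of pairwise mixed graphical models
    (Gaussian and Bernoulli nodes) on cohort tables, in the style of
    psychometric network analysis. Provides nodewise L1-penalized
    regression with extended-BIC model selection and AND-rule edge
    aggregation, node predictability, signed-network centrality indices
    and shortest-path mediation reports, spinglass and signed-Louvain
    community detection with consensus clustering of individuals,
    nonparametric bootstrap confidence intervals and edge-difference
    tests, case-dropping centrality stability, Welch group-difference
    tables with Bonferroni correction, and a Gibbs-sampler cohort
    generator for the same model class so that every stage of the
    pipeline can be exercised and validated on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
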