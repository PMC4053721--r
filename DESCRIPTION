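Package: voomde
Title: Precision Weights and Moderated Inference for RNA-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of RNA-seq read counts via
    observation-level precision weights (voom). Log-counts-per-million are
    modelled with gene-wise linear models; a robustly smoothed mean-variance
    trend converts fitted log-counts into inverse-variance weights, which feed
    weighted least squares and empirical Bayes variance moderation with
    moderated t and F statistics, false discovery rate control and log-odds
    of differential expression. Includes TMM and quantile normalization,
    weight-aware self-contained (rotation) and competitive gene set tests, a
    negative binomial count simulator with known truth labels, and an
    evaluation harness for type I error, power and false discovery curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    jsonlite,
    Matrix
Config/testthat/edition: 3
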