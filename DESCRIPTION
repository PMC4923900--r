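Package: profclust
Title: Time-Course Expression Profile Regression and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage maSigPro-style analysis of treatment-versus-control
    time-course expression experiments on a log-transformed time scale:
    per-probe polynomial regression with a global F-test significance filter,
    backward stepwise term selection, an R-squared stringency filter, and
    k-means clustering of fitted temporal profiles with data-driven selection
    of the number of clusters (including the degenerate zero-cluster outcome).
    Includes a synthetic-data generator with planted temporal templates and
    ground truth for recovery benchmarking, per-time-point Welch differential
    expression with Venn overlap summaries, and the supporting phenotype
    statistics layer (batch-blocked two-way ANOVA, standard errors of
    differences, and Monte-Carlo Dunnett many-to-one comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
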