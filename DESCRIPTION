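Package: seqpower
Title: Power and Error Simulation for RNA-Seq Differential Expression Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based evaluation of experimental designs for detecting
    differential expression from RNA-Seq read counts. Provides a hierarchical
    negative-binomial count simulator with an empirically motivated
    mean-dispersion power law, induced differential expression via exponential
    regulating factors, without-replacement depth subsampling (multivariate
    hypergeometric), an exact conditional negative-binomial two-group test with
    several dispersion-estimation strategies (empirical-Bayes tagwise
    squeezing, maximum of per-transcript and parametric-trend estimates, and a
    global power-law fit), Benjamini-Hochberg adjustment, fold-change calling,
    and false/true positive rate metrics. An orchestration layer runs null
    calibration experiments, replication-by-depth power grids and multiplex
    (barcoded lane sharing) scenarios with repetition summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
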