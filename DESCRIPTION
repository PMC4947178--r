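Package: editvar
Title: Cell-to-Cell Variance in RNA Editing Rates from Single-Cell and
    Bulk RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies cell-to-cell variance in C-to-U RNA editing rates
    at single genomic sites by combining single-cell and bulk RNA-seq read
    counts in a hierarchical beta-binomial model. The variance of the
    per-cell editing rates carries a penalized-complexity prior built from
    the Kullback-Leibler distance to the no-variability base model, and is
    sampled by a Metropolis-within-Gibbs scheme; inference is summarised
    through highest-posterior-density intervals, posterior-predictive
    marginal editing-rate draws and beta-kernel density estimates. Also
    includes a generator for the artificial single-cell data sets used to
    validate the model, and a bulk wild-type versus knockout editing-site
    caller based on the angle between per-site base-count vectors with
    annotation-driven exclusion filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
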