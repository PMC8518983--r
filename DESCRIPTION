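Package: rootEconomics
Title: Root Economics Phenomics: Respiration Flux, Trait Networks and
    Mixed-Model Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for root economics functional
    phenomics in crop diversity panels. Computes total root respiration from
    chamber CO2 accumulation traces via the ideal gas law, derives mass-,
    length- and volume-normalized root economics traits from image-analysis
    feature tables, partitions respiration among axial roots, lateral-root
    axes and lateral-root tips by multiple linear regression (yielding the
    residual respiration trait SRR_R), estimates broad-sense heritability by
    REML on a randomized complete block design, builds Pearson, PCA and
    Gaussian-graphical-model views of the trait space, and runs univariate,
    multivariate and principal-component genome-wide association scans with
    a centered kinship matrix. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    MASS,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
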