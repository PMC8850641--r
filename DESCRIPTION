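Package: spongenet
Title: Inference of lncRNA-miRNA-mRNA Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Spongenet", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a competing endogenous
    RNA (ceRNA) network inference pipeline for two-condition RNA-seq designs:
    differential-expression calling at fixed fold-change and FDR thresholds,
    positional lncRNA classification, a small-RNA annotation cascade,
    seed-match miRNA target prediction, correlation-based pair filtering
    (Spearman for miRNA-target repression, Pearson for lncRNA-mRNA
    co-expression), a hypergeometric shared-sponge test, triad assembly with
    Cytoscape-ready export, and hypergeometric term over-representation
    analysis. Ships a synthetic-data generator with planted ground truth
    (differential features, seed sites, ceRNA triads) so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
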