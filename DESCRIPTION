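Package: methexpand
Title: DNA Methylation Time-Course Analysis of Expanded T-Cell Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of Infinium-style DNA methylation array time courses
    from in vitro expanded regulatory T-cell products. Provides probe quality
    filtering, quantile normalization, beta/M conversion, empirical-Bayes
    batch adjustment, moderated-t differential methylation at single CpGs,
    kernel-smoothed differentially methylated region (DMR) calling with
    Stouffer combination, cross-run shared-DMR matching with Early/Late
    kinetic classification, partially methylated domain (PMD) and
    Treg-identity stability scoring against cumulative expansion rate,
    exhaustion-DMR concordance from bisulfite count data, over-representation
    and preranked gene-set enrichment statistics, and a synthetic-data
    generator with planted ground truth that makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
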