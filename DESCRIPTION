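Package: stromasig
Title: Stroma-Induced Chromatin and Expression Integration and the
    Sigma-ASI Prognostic Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline linking stroma-induced chromatin
    accessibility changes to gene expression in myeloma cells, and a
    decile-sum prognostic classifier built on the resulting gene signature.
    Provides negative-binomial differential testing of peak and gene count
    matrices with Benjamini-Hochberg FDR control, TAD-constrained assignment
    of cis-regulatory elements to proximal target genes, concordance and
    enrichment statistics (Fisher exact over-representation, hypergeometric
    overlap), consensus forward/backward stepwise Cox proportional-hazards
    gene selection, the Sigma-ASI decile-sum score with survival and
    therapeutic-resistance validation, and weighted Kolmogorov-Smirnov gene
    set enrichment with phenotype-permutation significance. A synthetic-data
    module generates genome annotations, coupled ATAC/RNA co-culture count
    matrices and patient cohorts with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
Config/testthat/edition: 3
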