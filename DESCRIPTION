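Package: regelex
Title: Dissecting Noncoding GWAS Risk Loci Through Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for interrogating noncoding GWAS
    risk loci with chromatin accessibility data: LD expansion and
    single-causal Bayesian fine-mapping into credible sets, activity
    calling on regulatory-element atlases, differential ATAC-seq analysis
    with loess MA-trend normalization, beta-binomial tests of
    allele-specific accessibility, desk-scale stratified LD-score
    regression for annotation heritability enrichment, permutation tests
    of risk-variant/element overlap, and motif/eQTL integration for gene
    prioritization. Ships a synthetic-data module that emulates the
    statistical structure of the real inputs (LD-block haplotypes,
    annotation-weighted GWAS summary statistics, negative-binomial element
    counts, beta-binomial allelic read counts) so every stage can be
    exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
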