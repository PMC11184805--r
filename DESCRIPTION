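Package: hybridomics
Title: Methylation, Expression and Variant Analysis of Parent-Hybrid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two parental accessions and their stabilized
    hybrid across three molecular layers. Scores cytosine methylation at CCGG
    sites from paired HpaII/MspI (MSAP) band patterns and calls demethylation
    and hypermethylation events in the hybrid; performs negative-binomial Wald
    tests for differential expression with median-of-ratios normalization;
    selects the number of expression clusters by the gap statistic, runs
    k-means on Z-scored profiles and assigns clusters to parent- or
    hybrid-specific expression categories; hard-filters SNPs, calls zygosity
    from allelic balance, classifies codon-level variant effects and computes
    a SNP-expression concordance statistic; and tests gene lists for GO term
    over-representation with the hypergeometric distribution. A synthetic-data
    generator with planted ground truth drives every stage so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
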