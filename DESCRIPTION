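Package: varfunnel
Title: Combined Genomic-Transcriptomic Prioritization of Family Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A variant prioritization funnel that combines case-control
    differential expression of vascular-wall transcriptomes (moderated
    t-test with empirical-Bayes variance shrinkage and Benjamini-Hochberg
    adjustment), a GWAS-catalog derived disease gene set, a family-based
    vertical-transmission filter on whole-exome genotypes, strand-aware
    transcript consequence annotation (missense, synonymous, stop-gained,
    UTR, intronic), low-frequency variant selection, and case-control
    allele-frequency comparison by a pooled two-proportion z-test with a
    Bonferroni-tiered significance classification. Includes a full
    synthetic-data generator (expression matrices, GWAS catalog exports,
    pedigrees with Mendelian genotypes, population allele-frequency tables
    and transcript models) with planted signal so every stage and the
    end-to-end funnel can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
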