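Package: mlmaSig
Title: Significance Testing and Genomic Control for Mixed Linear Model GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study significance testing in single-SNP mixed linear
    model association (MLMA) analyses of family-structured livestock
    populations. Provides pedigree (A), genomic (VanRaden method 1, Yang et
    al.) and leave-one-chromosome-out (LOCO) relationship matrices,
    eigendecomposition-based REML, single-SNP association scans with optional
    fixed SNP covariates, genome-wide and per-chromosome genomic control,
    and four significance-threshold procedures: phenotype-permutation
    thresholds, Bonferroni on the total SNP count, Bonferroni on the
    effective number of independent chromosome segments (Me), and
    Benjamini-Hochberg / Benjamini-Yekutieli false discovery rates. A
    pedigreed population simulator with LD-structured founder haplotypes,
    gene dropping and QTL plus polygenic phenotypes makes every stage
    testable without restricted breeding-company data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
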