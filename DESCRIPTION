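Package: parth2
Title: Partitioned SNP-Heritability, Gene-Set Enrichment and Polygenic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for partitioning the SNP-heritability of a
    quantitative trait across genomic regions defined by an a-priori gene set
    (gene bodies, flanking buffers of configurable width, and the rest of the
    genome). Provides PLINK BED/BIM/FAM and GCTA binary GRM readers and
    writers, marker quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, missingness), genomic relatedness matrices,
    average-information REML variance-component estimation with likelihood
    ratio tests, heritability enrichment statistics with fixed-effects
    meta-analysis across power-calibrated sample subsets, mixed-model
    association with leave-one-chromosome-out relatedness matrices, gene-set
    overlap statistics (Jaccard, Fisher exact, permutation), and
    summary-based BLUP polygenic scores with partitioned scoring. Includes a
    block-LD genotype and phenotype simulator so the whole pipeline is
    testable without restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
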