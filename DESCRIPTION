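Package: lemnapop
Title: Population Genomics of Clonal Duckweed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing Lemna minor from cryptic triploid
    L. japonica hybrids and for characterising clonal population structure
    from whole-genome SNP data. Implements the variant filters used for
    pond-collected duckweed cohorts, allele-sharing genetic distances,
    a reference-free canonical k-mer kinship, a per-SNP quasibinomial GLM
    scan for species assignment markers, allele-balance ploidy and hybrid
    sub-genome dosage inference, sub-genome coverage tests, and
    permutation-based structure statistics (multivariate dispersion,
    Mantel tests, isolation by distance). A synthetic-cohort generator
    emulates clonal within-pond populations, Balding-Nichols drift,
    spatial isolation by distance, triploid hybrid dosage and
    diploid-model genotype calling, so the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    geosphere,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
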