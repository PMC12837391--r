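Package: hapblup
Title: Single-Step GBLUP and ssGWAS with LD Haplotype Blocks and Pseudo-SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares three sources of genomic information for genomic
    prediction in dairy cattle: all quality-controlled SNPs, haplotype
    alleles of high linkage-disequilibrium blocks recoded as pseudo-SNPs,
    and only the high-LD SNPs that form the blocks. Implements pedigree
    relationship matrices and their sparse inverses, VanRaden genomic
    relationship matrices, the single-step H inverse, Henderson mixed-model
    equations for a repeatability animal model with herd-year-season and
    age-class fixed effects and permanent-environment and sire-herd random
    effects, back-solving of marker effects from genomic breeding values
    with normal-score p-values and Bonferroni thresholds, explained genetic
    variance, and prediction-error-variance reliabilities. A synthetic
    population generator (pedigree, block-structured founder haplotypes,
    gene dropping, QTL effects, repeated lactation records) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
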