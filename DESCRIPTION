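Package: ibdwindow
Title: Pairwise Relatedness from SNP Genotypes via Informative IBS and
    Windowed Bayesian IBD Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers pairwise genetic relatedness from biallelic SNP
    genotype calls. Implements the IBS2* ratio statistic (the fraction of
    concordant-heterozygote calls among informative identity-by-state
    observations, with expectation 2/3 for unrelated members of one
    population) together with a Z-test and exact binomial test against
    that null, and a windowed Bayesian identity-by-descent estimator that
    scans overlapping windows of informative SNPs to produce estimates
    (K0, K1, K2) of the Cotterman coefficients of relatedness. Includes a
    rule-based relationship classifier, readers and writers for PLINK
    PED/MAP and TPED/TFAM text formats and a simple genotype matrix
    format, and a gene-dropping pedigree simulator with exact per-marker
    IBD truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
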