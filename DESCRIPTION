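Package: inbredpanel
Title: Population Structure and Diversity Analysis of Inbred SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-based population analysis of panels of
    inbred (expected-homozygous) lines typed at biallelic SNPs, as used in
    maize heterotic-group studies. Covers merging of partially overlapping
    marker platforms with full accounting, quality-control filtering (minor
    allele frequency, site missingness, heterozygote and tertiary-call
    conversion), forward Markov-chain imputation with masked-data accuracy
    estimation, linkage-disequilibrium r-squared decay curves, principal
    component analysis, Nei's standard genetic distance with Ward
    hierarchical clustering and Newick export, and per-locus Weir-Cockerham
    F_ST scans with moving-window region extraction and candidate-gene
    queries. Includes a structured-panel simulator (Balding-Nichols group
    divergence plus cross-and-self pedigrees) that provides ground truth
    for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
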