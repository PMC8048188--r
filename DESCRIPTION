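Package: plastisel
Title: Plasticity and Selection Dynamics from mRNA-Derived SNPs and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of mRNA-derived genetic variation and
    expression for two-population studies: SNP and microsatellite filter
    cascades (quality, minor allele frequency, missingness, exact
    Hardy-Weinberg test, within-cluster linkage-disequilibrium pruning),
    population-genetic estimators (observed heterozygosity, Nei gene
    diversity, FIS, pairwise Weir-Cockerham FST, population-specific
    allele-matching FST) with locus bootstrap confidence intervals, two
    outlier-SNP scans (principal-component Mahalanobis scan with genomic
    inflation correction, and a label-permutation FST scan), three
    transcriptome plasticity tests (negative-binomial differential gene
    expression, differential exon usage with Simes aggregation, and a
    dispersion likelihood-ratio test for gene expression variability), and
    a gene-level selection-by-plasticity contingency analysis. Includes a
    Balding-Nichols genotype simulator and a negative-binomial count
    simulator with planted effects so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    vcfR,
    edgeR,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
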