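Package: gcdhscan
Title: Genome-Wide Collapsed Double-Heterozygosity Association Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects compound-heterozygote-like association signals between a
    quantitative trait and pairs of nearby SNPs. Pairs of variants inside a
    sliding genomic window are collapsed into pseudo-markers through a
    collapsing matrix (recessive or additive), each pseudo-marker is tested
    in a covariate-adjusted linear model, and the per-window minimum P value
    is assigned to the window's index SNP (the GCDH test). The package also
    provides a conventional single-SNP GWAS stage with genomic-control
    diagnostics, a phenotype-permutation empirical null for the scan,
    two-locus haplotype EM to separate compound (trans) from double (cis)
    heterozygotes at significant pairs, polygenic-score construction with an
    iterative variance-explained ledger, exact replication testing, and a
    synthetic-cohort generator with LD-blocked haplotypes and planted single
    and pair effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
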