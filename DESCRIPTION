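Package: snpsetmeta
Title: Multi-Cohort SNP-Set Association Testing by Permutation with
    Weighted Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained SNP-set association testing of candidate gene
    groups against quantitative phenotypes by phenotype permutation, with
    square-root-of-N weighted Stouffer combination of empirical p-values
    across cohorts.  Also provides per-SNP additive association scans with
    fixed-effects inverse-variance meta-analysis, gene-based p-values by
    simulation from a multivariate-normal null that accounts for linkage
    disequilibrium, competitive gene-set enrichment via a weighted
    running-sum Kolmogorov-Smirnov statistic, and a Monte-Carlo power study
    for the meta-analysed set test under varying numbers of effect SNPs and
    variance fractions.  A synthetic-data module generates multi-cohort
    genotype, covariate and test-battery data with the statistical
    structure the analysis assumes (LD blocks, population structure, a
    latent-factor test battery), so the whole pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    fgsea,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
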