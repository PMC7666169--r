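Package: rohid
Title: Runs of Homozygosity and Inbreeding-Depression Analysis for
    Quantitative Traits
Version: 0.1.0
Authors@R:
    person("AWI", "Genomics Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls runs of homozygosity (ROH) from SNP genotypes with the
    classic sliding-window algorithm, computes genomic inbreeding
    coefficients (F_ROH, F_GRM, F_outsideROH), and estimates
    inbreeding-depression effects on quantitative traits via a two-step
    polygenic-residual regression with sex- and urbanization-stratified
    variants, bivariate F_ROH/F_GRM conditioning, and a genome-wide scan
    of ROH burden in 3-Mb windows. Includes a synthetic-cohort generator
    with known autozygosity and known directional-dominance architecture
    so that every stage of the pipeline can be validated against ground
    truth, plus readers/writers for PLINK 1 binary and VCF genotypes and
    the QC filters typically applied before ROH analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
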