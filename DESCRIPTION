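Package: haploSweep
Title: Selection-Signature Scans from Phased Haplotypes (iHS and Global FST)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic signatures of recent positive selection in
    multi-population panels of phased, complete biallelic genotypes. Implements
    the within-population integrated haplotype score (iHS) built on extended
    haplotype homozygosity (EHH) decay, with derived-allele-frequency-binned
    standardization, a Gaussian two-sided p-value transform, fixed-width genome
    window aggregation and false-discovery-rate calling; and an
    across-population scan based on the global multi-population Weir-Cockerham
    FST estimator with empirical top-fraction thresholding. Includes gene
    annotation of significant windows and SNPs, intersection of the two
    methods' gene hits, cohort descriptors (pedigree inbreeding coefficients,
    Euclidean genotype distances, minor-allele-frequency summaries), and a
    seeded synthetic-data generator producing phased multi-population panels
    with known truth (neutral recombination mosaics, hard sweeps, F-model
    drift) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
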