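Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Population Structure
    for SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid SNP-array
    genotypes with the consecutive method, summarises them per sample,
    chromosome and length class, and calls high-incidence ROH islands with
    optional gene-interval annotation.  Computes two genomic inbreeding
    coefficients (excess homozygosity F and FROH), pairwise Weir-Cockerham
    FST, principal components and per-group monomorphic-marker counts.
    Includes plain-text PLINK PED/MAP input/output and a synthetic
    multi-population genotype simulator with known autozygosity tracts,
    Balding-Nichols differentiation and a four-way hybrid-cross mode, so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
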