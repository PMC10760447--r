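Package: ssdskit
Title: Simulation and Homolog-Resolved Analysis of Strand-Specific ssDNA
    Maps of Meiotic Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-stranded DNA sequencing (SSDS) maps
    of meiotic recombination intermediates in F1-hybrid genomes. Provides a
    forward simulator of strand-specific ssDNA fragments arising from
    resected double-strand breaks at PRDM9-positioned hotspots (with truth
    labels for haplotype and repair role), Poisson peak calling with
    background-corrected intensities, SNP-based haplotype assignment and
    hotspot symmetry classification, oriented strand- and homolog-resolved
    aggregate binding profiles, nonnegative least-squares deconvolution of
    per-break protein footprints, and cross-genotype hotspot intensity
    comparison with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    withr,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
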