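Package: clonintro
Title: Introgression Scans, Genetic Load, and Forward Simulation for
    Clonally Propagated Crops
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Windowed population-genomic statistics (nucleotide diversity,
    Dxy, Hudson's FST, the population branch statistic, per-sample
    heterozygosity and method-of-moments identity-by-descent), the
    ABBA-BABA family of introgression statistics (D, fd, fdM and the
    tree-aware f-branch summary), deleterious-load accounting stratified
    by genomic region class, and a diploid Wright-Fisher forward
    simulator contrasting outcrossing with clonal propagation after a
    hybridization pulse.  A synthetic-data module generates a
    five-population dataset with known introgressed ancestry tracts so
    that every stage of the pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    ape,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
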