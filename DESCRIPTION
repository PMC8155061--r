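Package: indelmapr
Title: Fast Genetic Mapping with Large Insertion-Deletion Markers in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for PCR-based genetic mapping in Caenorhabditis elegans using
    insertion-deletion polymorphisms with 40-699 bp length change between the N2
    reference strain and wild isolates such as CB4856. Builds and filters indel
    marker catalogs with nearest-gene annotation, scores wild isolates for
    genome-wide marker coverage in 1 Mb windows, validates and selects 96-well
    PCR marker panels under product-size and melting-temperature constraints,
    simulates the CB4856 x mutant F2 mapping cross with a Haldane crossover
    model and a band-detection model for pooled lysate PCR, calls the
    mutation-containing interval from pooled band patterns and refines it with
    individual F2 genotypes, and estimates the expected number of candidate
    mutations in a mapped interval from mutagenesis burden statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
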