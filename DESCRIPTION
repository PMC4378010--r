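Package: riboflux
Title: Gene- and Codon-Level Translation Efficiency from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bacterial ribosome profiling (RP) and mRNA-seq
    libraries at gene and codon resolution. Computes RPKMc depth and the
    RP/mRNA (R/m) translation-efficiency ratio, SAM-style permutation
    selection of discordantly translated genes, the codon adaptation index,
    metagene profiles anchored at the gene 5' end, A-site offset calibration
    from the 3' ends of footprints, and relative ribosome densities of the
    61 sense codons at nucleotide resolution around the decoding site.
    Includes a footprint and mRNA-read simulator with codon-specific dwell
    times, initiation pausing, drug-mode artifacts and poly(A) 3'-end
    ambiguity, providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
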