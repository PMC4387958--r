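Package: popgenscan
Title: Multi-Caller Variant Filtering, Population-Genomic Diversity, and
    Selective-Sweep Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-genome population-genomics toolkit built around three
    stages: consensus filtering of variant calls from multiple callers with a
    Gaussian recalibration score (VQSLOD) and a robust median - 3*MAD cutoff;
    neutral diversity and structure statistics (nucleotide diversity,
    per-individual heterozygosity and inbreeding, identity-by-state,
    transition/transversion ratio, minor-allele-frequency spectrum,
    Weir-Cockerham FST, linkage-disequilibrium decay and pruning, PCA); and a
    cross-population composite-likelihood (XP-CLR) scan for selective sweeps
    with segment-wise score assembly and gene mapping.  Mitochondrial
    control-region haplotype statistics and a Balding-Nichols founder-mosaic
    simulator with known truth round out the pipeline, so every stage is
    testable end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
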