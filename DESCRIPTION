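Package: meioscape
Title: Meiotic Crossover Landscapes and Bisulfite Methylome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing male meiotic recombination landscapes from
    backcross (BC1) SNP genotyping and for comparing whole-genome bisulfite
    methylomes between two genotypes. The recombination track calls crossover
    breakpoints from three-state genotype matrices, builds Kosambi genetic
    maps with confidence intervals, compares interval crossover rates between
    populations under the Benjamini-Krieger-Yekutieli two-stage FDR
    procedure, fits exponential crossover-rate gradients relative to
    centromeres and telomeres, and contrasts inter-crossover distances
    against a random-placement null. The methylome track annotates cytosine
    contexts (CG/CHG/CHH) from a genome sequence, applies coverage
    filtering, computes weighted methylation levels in genome tiles and
    metagene profiles over genes and transposable elements, tests per-site
    differential methylation with Fisher exact tests on pooled counts, and
    calls differentially methylated regions through a length / DML-count /
    significant-fraction / effect-size rule chain with gap merging. Seeded
    synthetic-data generators (crossover landscapes with gamma-renewal
    interference; paired cytosine reports with planted hypermethylated
    transposable elements) provide ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    vctrs,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
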