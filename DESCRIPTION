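Package: paleoploid
Title: Whole-Genome Duplication Inference and Post-Duplication Ohnolog Fate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ancient whole-genome duplication (WGD) from chromosome-level
    gene annotations and proteomes: all-vs-all protein homology search and
    filtering, collinear (syntenic) paralog block detection by dynamic-programming
    chaining, duplicate-gene classification, paralogous chromosome pairing from
    interchromosomal best-hit paralogs, synonymous-substitution (Ks) age
    distributions from protein-guided codon alignments with transition/transversion
    corrected distances, Ks peak dating and WGD-versus-speciation event ordering,
    duplicated single-copy-ortholog (BUSCO-style) statistics and conserved
    (Hox-like) cluster scanning, expression-based classification of ohnolog fates
    (nonfunctionalization, neo-/subfunctionalization) under a tidal-exposure
    design, and OPLS-DA/VIP differential-metabolite calling. Includes a forward
    genome-evolution simulator producing truth-labelled genomes, expression
    matrices and metabolomes for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    GenomicRanges,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
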