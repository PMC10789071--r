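Package: diffabc
Title: Differential Activity-by-Contact Analysis of Enhancer-Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes activity-by-contact (ABC) enhancer-gene scores built from
    ATAC-seq and H3K27ac HiChIP into chromatin-accessibility (ATAC), activity
    (ChIP, vanilla-coverage square root) and contact (HiC) components per sample,
    tests each component for between-ancestry differences with a replicate-shuffle
    permutation FDR, and runs the downstream enrichment, directionality-matching,
    Weir-Cockerham FST and binomial sign-test selection analyses. Ships a
    synthetic-data generator that emulates the pooled 14-sample two-ancestry study
    design with known injected effects so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
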