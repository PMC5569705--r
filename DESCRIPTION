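Package: mirtronkr
Title: Design and Validation of Artificial Mirtrons for Knockdown-Replacement Gene Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for engineering artificial mirtrons, introns that are
    spliced out of a host transcript and fold directly into pre-miRNA hairpins,
    and for building knockdown-replacement (KR) constructs around them.
    Provides splice-constrained RNAi target-site discovery on a transcript,
    mirtron hairpin assembly with passenger-strand editing for polypyrimidine
    tract quality and RISC strand bias, nearest-neighbor duplex free-energy
    estimation, splice-signal and exonic-splice-enhancer (ESE) scoring of
    candidate intron insertion sites in a replacement transgene, synonymous
    recoding of the transgene for RNAi resistance, control-variant generation
    (unspliceable, shRNA, destabilized), and small-RNA sequencing analytics
    (arm fractions, 5'-end fidelity, length distributions) with a matched
    seeded read simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
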