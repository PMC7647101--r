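Package: pepdau
Title: Differential Amino Acid Usage Analysis of Anchored Peptide Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Position-specific testing and visualization of differential amino
    acid (and amino-acid group) usage in sets of anchored peptides, such as
    protease substrates centered on cleavage sites, kinase substrates centered
    on phosphosites, or protein N-termini. Peptide windows are compared against
    configurable proteome-derived background models (twelve combinations of
    proteome-level, positional, and anchoring constraints) using either a
    bootstrap Z-test with binomial standard errors or Fisher's exact test.
    Amino acids can be collapsed onto reduced alphabets grouped by charge,
    hydrophobicity, or side-chain size before testing. Results are rendered as
    significance-aware sequence logos (over-represented symbols above the axis,
    under-represented below, heights in percentage-point frequency difference)
    and as Z-score heatmaps. A synthetic proteome and peptide-set generator
    with planted per-position enrichments supports calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
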