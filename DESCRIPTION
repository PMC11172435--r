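Package: codoncontext
Title: Codon Adjacency Statistics and A-Site Ribosome Density by +1 Codon Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies codon-adjacency preferences in coding sequences and the
    dependence of ribosome dwell on the codon 3' of the A site. Builds
    position weight matrices of log2 observed/expected nucleotide frequencies,
    conditionally on the identity of the preceding codon; classifies codons by
    wobble nucleotide and tRNA position-34 identity (G34/I34); converts
    ribosome footprint 5'-end counts into per-codon normalized densities with
    A-site offsetting, three-nucleotide frame assignment and per-gene
    normalization; and compares A-site codon densities with versus without a
    +1 GNN codon using gene-level bootstrap resampling. A synthetic-data
    module generates ORF sets and footprint profiles with known injected
    adjacency and dwell effects for recovery and calibration testing.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
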