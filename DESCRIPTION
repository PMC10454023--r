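Package: nucleosurvey
Title: Genomic Survey of Bacterial ushA-Like and cpdB-Like Nucleotidase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey the distribution of genes encoding periplasmic or
    cell wall-bound bacterial nucleotidases (UshA-like 5'-nucleotidases and
    CpdB-like 3'-nucleotidases) across a taxonomy of complete genomes. Provides
    a desk-scale translated homology search (six-frame translation plus local
    protein alignment with bit-score and query-coverage hit filtering), probe
    panel management with relatedness grouping and greedy probe selection, a
    hierarchical presence/absence survey engine with completeness-based
    pruning, cross-probe per-genome reconciliation and correlation
    tabulation, and a deterministic synthetic genome generator with planted,
    divergence-controlled homologs for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
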