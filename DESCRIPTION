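Package: wordsamp
Title: Optimal Word-Based Sequence Sampling Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and tools for sampling positions in nucleotide sequences
    with word-based schemes (sets of fixed-length words over a reduced
    purine/pyrimidine alphabet), minimizers' relatives such as open and closed
    syncmers, and positional every-s-th schemes. Computes exact run-hitting
    probabilities by dynamic programming, optimizes word sets by exhaustive
    search or simulated annealing, analyses minimum/maximum separation (polar
    and universal hitting sets), and evaluates downstream seed sensitivity and
    specificity: the expected fraction of maximal exact matches sampled, the
    expected letter coverage, and the distribution of distances between
    sampled positions. Includes seeded synthetic-sequence generation and
    empirical sampling of FASTA sequences with BED output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    data.table,
    generics,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
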