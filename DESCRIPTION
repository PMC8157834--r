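Package: asvpost
Title: Post-Denoising Utilities for Amplicon Sequence Variant Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-denoising toolkit for amplicon-sequencing feature tables.
    Removes between-sample crosstalk (index hopping) with an expected-leak
    model, resolves N-concatenated variable-length paired amplicons by
    overlap merging, renders octave plots (log2-binned abundance
    histograms), simulates communities with known leak and overlap ground
    truth, and writes input bundles for downstream numerical-ecology tools
    (Rhea, MicrobiomeAnalyst, phyloseq).
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    optparse,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
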