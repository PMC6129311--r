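Package: tissueweights
Title: Tissue-Specific Gene Set Weights from RNA and Protein Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tissue-specific weights for gene sets by combining
    RNA-seq expression fold-changes with immunohistochemistry (IHC) protein
    detection calls, in the style of the Human Protein Atlas normal-tissue
    data. Per-gene, per-tissue weights are aggregated into per-set tissue
    weights with a competitive one-sided two-sample t-test on the -log
    p-value scale, supporting tissue characterization, multi-tissue
    (minimum-weight) profiling, and weighted Benjamini-Hochberg false
    discovery rate control for gene set testing p-values. Includes readers
    for GMT gene set collections and tab-separated expression/IHC tables, a
    synthetic data generator with planted tissue-specific gene sets, ggplot2
    visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
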