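Package: mutscape
Title: Mutation Landscape Profiling for Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the somatic mutation landscape of cancer
    cell-line panels from MAF-like mutation tables. Implements the filter
    cascade used for hybrid-capture cell-line mutation calls (intronic and
    silent records, low allelic fractions, the NOTCH4 exon-1 repeat
    polymorphism, small cell-type strata), gene- and gene-family mutation
    frequencies with max-one-mutation-per-line deduplication and
    coding-length normalization, protein-domain mapping of mutations
    (EGF/NRR/PEST fractions, cysteine gain/loss scan, recurrent-position
    hotspots), functional-impact classification from subPSEC-style scores,
    GISTIC-style copy-number alteration summaries, and ranked cell-line
    versus primary-tumor frequency comparisons. Ships a synthetic cohort
    generator with known ground truth so every stage is testable without
    external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
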