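Package: bioidr
Title: Interaction Scoring and Differential Profiling for BioID
    Proximity-Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contaminant-aware analysis of BioID / AP-MS spectral-count
    experiments run against negative-control purifications. Implements
    fold-change (FC-A) and two-component Poisson interaction-probability
    scoring with stringent three-criterion hit selection, bait-abundance
    normalization, the pseudocounted log2 ratio R with a two-sample t-test
    for wild-type versus mutant differential interactome profiling,
    a label-permutation false discovery rate, hypergeometric gene-set
    fold-enrichment tests over GMT collections, and a negative-binomial
    generator of triplicate BioID experiments with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
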