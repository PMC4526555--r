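Package: tormir
Title: Small RNA Discovery and Hibernation Differential Expression Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for pooled small RNA sequencing studies of
    hibernation physiology. Implements read cleaning and collapsing, exact
    genome mapping with multi-locus and singleton filters, annotation-based
    read classification, novel microRNA hairpin discovery (genomic block
    merging, inverted-repeat dynamic programming, weighted base-pair
    maximisation folding, hairpin structure criteria, mature calling),
    TPM quantification with a conditional negative-binomial exact test for
    libraries without replicates, site-accessibility (delta-delta-G) miRNA
    target prediction with 3'UTR inference, hypergeometric enrichment,
    miRNA-mRNA link construction, and stem-loop qPCR 2^-ddCt validation.
    A synthetic-data module plants hairpin precursors, decoy annotations and
    negative-binomial counts with known truth so that every stage can be
    exercised against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
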