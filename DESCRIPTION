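Package: wellnets
Title: Co-Occurrence Network Ensembles from Dilution-Series Cultivation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ensembles of microbial co-occurrence networks from
    dilution-to-extinction 96-well cultivation arrays. Builds one signed,
    thresholded Spearman correlation network per plate (prevalence filter,
    tie-corrected rank correlation, Benjamini-Hochberg FDR, degree-centrality
    sub-network), aggregates plates into the cross-network pair-prevalence
    statistic FO = Np/Ng to extract robust prevalent taxon pairs, matches
    cultured isolates to Zotus by 16S V4 identity and neighbor-joining tree
    proximity, and classifies pairwise interactions (mutualism through
    competition) from mono- versus co-culture growth data quantified by qPCR
    standard curves. A synthetic plate-array generator with planted
    interactions makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
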