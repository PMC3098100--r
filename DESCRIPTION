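Package: unifynet
Title: Rule-Based Unification of Biological Records and Interaction
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous biological databases by unifying
    their records into equivalence classes ("user entities") under
    user-defined rule sets, with special handling of promiscuous sources
    such as structural-domain classifications.  Builds interaction
    networks over the unified entities by seed-based breadth-first
    expansion with relation-attribute restrictions, supports tagging,
    linker degrees, degree-preserving randomization and network set
    algebra, predicts new edges by transferring observed relations to
    entities that share attributes or pass sequence-similarity and
    coverage cutoffs (generalized interologs), and backtracks every
    unified node to its source records and the rule firings that fused
    them.  Readers are provided for a generic tabular record format,
    PSI-MI TAB 2.5 and FASTA; networks export to SIF and a provenance
    TSV.  A deterministic synthetic-data module generates all fixtures.
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
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
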