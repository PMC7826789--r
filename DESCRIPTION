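Package: kinoset
Title: Assembly and Annotation of Kinase Chemogenomic Inhibitor Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and annotating chemogenomic sets of kinase
    inhibitors from broad-panel kinome profiling data. Computes activity
    profiles and the S10 selectivity index from percent-of-control matrices,
    applies potency/selectivity inclusion filtering against dissociation
    constant follow-up tables, assigns compounds to hinge-binder chemotype
    bins by priority-ordered SMARTS substructure matching, assembles a set by
    a deterministic greedy algorithm that maximizes kinome coverage at a
    target chemotype depth, reports family-level and dark-kinase coverage,
    generates 384-well plate maps with assay-budget arithmetic, and annotates
    downstream phenotypic screens (normalized growth-rate inhibition,
    cytotoxicity tiers, autophagic-flux hit calling). Includes seeded
    synthetic-data generators with embedded ground truth for every input the
    toolkit consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
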