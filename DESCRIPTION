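Package: affnet
Title: Rare-Variant Filtering, Gene Recurrence and Seed-Gene Interaction
    Subnetworks for Atypical Femoral Fracture Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an exome-cohort inference chain for bisphosphonate-
    associated atypical femoral fractures (AFF): quality and rarity filtering
    of annotated variant calls, control subtraction, damaging-variant
    prioritization (SIFT/PolyPhen/CADD), cross-patient gene-recurrence
    classification, candidate gene-set intersection with hypergeometric
    enrichment, shortest-path skeleton extraction over an integrated
    interactome (Dijkstra with tied-path unions), and a two-group
    differential-expression overlay with empirical-Bayes variance moderation.
    Includes seed-deterministic synthetic-data generators with recorded ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
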