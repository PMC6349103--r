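Package: skeletax
Title: Carbon-Skeleton Extraction and Chemotaxonomic Analysis of Terpenoid Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for database-driven chemotaxonomy of terpenoid natural
    products. Extracts carbon skeletons (core alkanes) from compound
    structures by saturating all bonds and fragmenting at heteroatoms,
    canonicalizes and deduplicates skeletons by graph isomorphism, matches
    them against a reference library of diterpene skeletons with standard
    position numbering, maps compound occurrences onto a genus/clade
    taxonomy, computes skeleton distribution statistics and positional
    structural-pattern counts, and filters homology-search candidates by
    query coverage and identity with greedy identity-based merging of
    peptides. Ships a seeded synthetic-data generator that decorates known
    skeleton graphs into labeled compound libraries so every stage is
    testable without proprietary compound databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    ChemmineOB,
    yaml,
    utils,
    stats
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
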