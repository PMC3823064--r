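Package: specswap
Title: Substrate-Specificity Evolution in Aminotransferase Subfamily Ia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how substrate specificity
    (aspartate versus aromatic amino acids) evolved in subfamily Ia
    aminotransferases. Provides structure-anchored selection of moderately
    variable active-site alignment positions, distance-and-variability (D&V)
    divergence scoring and grouping of candidate enzymes, a permutation test
    of active-site conservation, group-conditional conserved-residue (Venn)
    sets, ping-pong bi-bi kinetic fitting with kcat/Km specificity-ratio
    classification, and binary-trait parsimony counting of specificity-switch
    events on a rooted phylogeny. Includes seeded generators for synthetic
    alignments, structures, kinetic assays and annotated trees so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
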