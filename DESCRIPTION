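Package: slcpipe
Title: Membrane Transporter Family Discovery from HMM Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and classifying solute
    carrier (SLC)-like membrane transporter families across proteomes.
    Profile-HMM hit tables are turned into per-protein bit-score
    fingerprints, redundant sequence fragments are collapsed to one
    representative per gene via an annotation/HSP graph, families are
    derived by cosine-distance UPGMA clustering with constrained tree
    cutting (join/split pairs), remote structural homologs are filtered by
    transmembrane-segment coverage and E-value, and orthologs across a
    fixed seven-species tree are extracted by LCA gene-tree/species-tree
    reconciliation with duplication-loss parsimony rooting. A synthetic
    data generator plants ground truth (families, fragments, structural
    accept flags, duplication/loss events) so that every stage is testable
    end to end without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
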