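Package: gpcrmine
Title: Genome-Wide GPCR Mining, Classification, and Expression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a planarian G protein-coupled
    receptor (GPCR) repertoire analysis: six-frame ORF discovery with
    end-curation flags, similarity-seeded receptor mining with a non-GPCR
    exclusion rule and a seven-transmembrane hydropathy topology filter
    iterated to a fixpoint; CLANS-style force-directed similarity networks
    with convex-cluster extraction and cross-species family labeling;
    neighbor-joining phylogenies with Jukes-Cantor distances, bootstrap
    supports and outgroup rooting; an RPKM biotype-comparison expression
    screen with a division-by-zero sentinel and trend-line fold-change
    normalization; receptor-activation (four-parameter logistic EC50) and
    qPCR delta-delta-Ct quantification; and seeded synthetic-data
    generators that emulate every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phytools,
    igraph,
    minpack.lm,
    mgcv,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
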