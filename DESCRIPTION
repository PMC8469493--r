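Package: orthoclade
Title: Tree-Based Ortholog Delimitation and Comparative Summaries for
    Seed-Mucilage Toolbox Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as a tested reusable pipeline, a comparative
    genomics workflow for the Arabidopsis thaliana mucilage secretory cell
    (MSC) toolbox genes across Brassicaceae: filtering of tabular BLAST
    hits (rank/e-value union rule), alignment gap-column trimming,
    outgroup rooting of gene-family trees, extraction of the focal clade
    and delimitation of the ortholog sub-clade bounded by the closest
    early-diverging anchor sequence (Aethionema arabicum), construction
    of the genes-by-species copy-number presence matrix with phenotype
    contrasts, and cross-species seed-development expression
    summarisation (kinetic SUM, top-10 reference, SUM%).  A synthetic
    data module provides a Brassicaceae-like species tree, a
    duplication/loss gene-family simulator with ground-truth ortholog
    sets, and expression-table generators, so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    phangorn
Config/testthat/edition: 3
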