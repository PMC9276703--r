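Package: screpair
Title: Single-Cell Analysis of Adaptive and Fibrotic Kidney Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting adaptive versus maladaptive (fibrotic) tissue
    repair from single-cell RNA-seq cohorts: cell and gene quality-control
    filters, injury-state signature derivation with correlation pruning and
    binned-control module scoring, a permutation test for differential
    cell-type proportions, metacell-based signed weighted coexpression
    network analysis (topological overlap, module eigengenes, kME hubs),
    ligand-receptor interaction permutation testing, and an L1000-style
    druggability screen built on prototype ranked lists and pre-ranked gene
    set enrichment. A synthetic-cohort generator with known ground truth
    (negative-binomial counts, planted markers, injury programs, doublets,
    low-quality cells and drug-response tables) supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
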