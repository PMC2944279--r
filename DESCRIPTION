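Package: tableauMatch
Title: Protein Substructure Search by Simulated Annealing over Tableaux
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Protein structure and substructure (motif) searching at the
    level of secondary structure elements (SSEs). Structures are encoded
    as tableaux (symmetric matrices of discrete two-character codes for
    pairwise SSE orientations, with SSE types on the diagonal) together
    with matrices of distances between SSE C-alpha centroids. Maximally
    similar subtableaux between a query and each database entry are
    extracted by simulated annealing with restarts, supporting
    non-sequential and substructure matchings under a distance-difference
    constraint. Includes construction of tableaux and distance matrices
    from PDB coordinates and DSSP secondary-structure assignments, a
    plain-text database format, size normalization of scores, ROC/AUC
    evaluation with Hanley-McNeil confidence intervals, and synthetic
    fixture generators with an exhaustive-search oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
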