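Package: supercomb
Title: Combining Overlapping Multi-Gene Data into Phylogenies: Superalignment,
    Supertree and Distance-Matrix Methods with a Simulation Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining overlapping multi-gene sequence data sets into
    a single phylogeny at three levels: early (superalignment by
    concatenation), medium (per-gene maximum-likelihood distances combined by
    averaging or by variance-minimizing super-distance-matrix scaling, fitted
    with missing-data-aware Fitch-Margoliash least squares) and late
    (matrix-representation supertrees with parsimony, irreversible parsimony,
    flipping and compatibility objectives; Build, MinCut and modified MinCut
    rooted-triplet supertrees; majority-rule and strict consensus). Includes a
    simulation engine for benchmarking the methods: Yule species trees, gene
    trees that are identical, rate-scaled or drawn from a multispecies
    coalescent, HKY+Gamma sequence evolution, empirical-style taxon-occupancy
    patterns, and an evaluation layer based on the normalized Robinson-Foulds
    distance, the single-gene baseline distance and paired Wilcoxon
    signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    igraph,
    phytools,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
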