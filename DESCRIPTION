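Package: winnow
Title: Information-Theoretic Window-Size Selection for Non-Overlapping
    Window Phylogenomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing the window size of a non-overlapping window
    (NOW) phylogenomic analysis of whole-genome alignments with the Akaike
    information criterion. Fits per-window Jukes-Cantor maximum-likelihood
    trees with a minimum-branch-length floor, aggregates AIC and BIC across
    windows for a grid of window sizes, and implements a stepwise
    pairwise-halving procedure that is robust to missing data in empirical
    alignments. Includes a multispecies-coalescent simulation framework
    (incomplete lineage sorting, introgression pulses, recombination) that
    retains the per-site true genealogy, plus site-accuracy and
    topology-weight RMSE metrics for validating the criterion against
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
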