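Package: introscape
Title: Phylogenetic HMM Scan for Introgressed Genomic Regions in a
    Four-Taxon Triplet
Version: 0.1.0
Authors@R:
    person("Ridge", "Hollandson", email = "ridge.hollandson@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes introgressed genomic regions between
    two nonsister species in a rooted four-taxon triplet. A two-parent-tree
    phylogenetic hidden Markov model (six hidden states: parent tree by
    gene-tree topology, Jukes-Cantor emissions via Felsenstein pruning) is
    fit by Baum-Welch with random restarts; forward-backward posterior
    decoding yields per-site introgression probabilities which are averaged
    over restarts, thresholded, and assembled into depth- and gap-filtered
    introgression tracts. Tracts are compared against the nonintrogressed
    species-tree background with interval-level absolute divergence (d_XY),
    Nei-Gojobori pairwise dN/dS, feature-density permutation tests,
    pooled-bootstrap comparisons of means, gene-family enrichment sampling,
    and a chromosome-absence block test. A seeded synthetic-data generator
    produces complete studies (quartet alignments with planted tracts,
    genotype qualities, depth tracks, gene annotations) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    data.table,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
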