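Package: microassembly
Title: Null-Model Assembly Processes, RMT Co-Occurrence Networks and
    Driver Attribution for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Partitions deterministic and stochastic assembly processes in
    microbial community data using phylogenetic (beta-nearest taxon index)
    and taxonomic (Raup-Crick with Bray-Curtis) null models, builds
    co-occurrence networks with a random-matrix-theory correlation
    threshold and classifies keystone taxa by within-module degree and
    participation coefficient, and attributes environmental parameters and
    keystone taxa to selection- or dispersal-related processes through PCA
    and distance-based redundancy analysis with forward model selection.
    Includes a regime-based community simulator (environmental filtering on
    phylogenetically conserved niche traits versus neutral sampling with
    tunable dispersal) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    phytools,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
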