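Package: pltscan
Title: Detection and Phylogenetics of Phage-Tail-Derived Gene Clusters in
    Prokaryotic Genomes
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Tools for finding phage-like protein-translocation structure
    (PLTS) gene clusters in annotated prokaryotic genomes and for placing
    them on a phylogeny.  The package scans genomes with a seed protein set
    using local alignment and reciprocal-best-hit confirmation, groups hits
    into candidate loci under configurable retention and extension rules,
    scores baseplate synteny against a consensus gene-order profile, builds
    concatenated-marker neighbor-joining trees from Poisson-corrected
    amino-acid distances with column-resampling bootstrap support, and
    quantifies gene-tree versus species-tree incongruence with
    Robinson-Foulds distances and a leave-one-out displacement ranking to
    flag horizontal-transfer candidates.  A fully seeded synthetic-data
    generator produces annotated genomes with planted clusters, decoys and
    known gene trees for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
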