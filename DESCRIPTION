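Package: PanPhylo
Title: Gene-Content Phylogeny and Marker-Gene Congruence for Algal Virus
    Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares large double-stranded DNA virus (phycodnavirus)
    genomes by the presence and absence of shared gene clusters and relates
    that variation to a conserved marker gene (family-B DNA polymerase).
    Provides greedy centroid clustering of predicted proteins at a
    fractional amino-acid identity threshold, gene presence-absence
    distances with neighbor-joining trees and cluster-resampling bootstrap
    support, pairwise maximum-likelihood protein distances under the WAG
    model, Mantel tests of congruence between distance matrices,
    calibration of amplicon clustering thresholds against full-length
    marker divergence, and OTU summarization of environmental amplicon
    samples with rarefaction.  A seed-controlled simulator of gene
    gain/loss/transfer along a phylogeny, marker-gene evolution, and
    environmental amplicon samples provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'PanPhylo-package.R'
    'AllClasses.R'
    'align.R'
    'cluster.R'
    'congruence.R'
    'distance.R'
    'io.R'
    'marker.R'
    'otu.R'
    'simulate.R'
    'tree.R'
    'wag.R'
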