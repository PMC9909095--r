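Package: oceancomm
Title: Community Assembly and Biogeography of Marine Microbial Metacommunities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the assembly and biogeography of marine
    microbial communities from amplicon count tables, a phylogeny and sample
    metadata: alpha diversity (Shannon-Wiener, Gini-Simpson, Pielou evenness,
    Faith phylogenetic diversity, Good's coverage), rarefaction, Hellinger
    transformation, Bray-Curtis dissimilarity and principal coordinates
    analysis; thresholded Spearman co-occurrence networks at the order level;
    the three-step phylogenetic null-model framework (beta mean nearest taxon
    distance, beta nearest taxon index and Bray-Curtis-based Raup-Crick)
    that partitions pairwise community turnover among heterogeneous selection,
    homogeneous selection, dispersal limitation, homogenizing dispersal and
    drift; and spatial-versus-environmental driver analyses (distance decay,
    Mantel tests, one-factor PERMANOVA, PCNM spatial eigenfunctions,
    redundancy analysis and variation partitioning). A synthetic
    metacommunity generator with depth-structured environmental gradients,
    phylogenetically conserved niche traits and known assembly regimes
    provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    geosphere,
    jsonlite,
    permute,
    phangorn,
    picante,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
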