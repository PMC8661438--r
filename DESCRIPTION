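Package: fishor
Title: Olfactory Receptor Gene Repertoire Evolution in Fish Genomes
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the birth-and-death evolution of the olfactory
    receptor (OR) gene repertoire in teleost fishes. Provides a translated
    local homology search engine with Karlin-Altschul e-value statistics and a
    frameshift-aware protein-to-DNA aligner; a two-pass OR gene mining and
    classification pipeline (functional, pseudogene, truncated, and
    scaffold-edge genes); gene-tree/species-tree duplication-loss
    reconciliation with per-branch birth and death rates; forward simulation
    of pseudogene sequence decay until homology-search undetectability;
    ancestral reconstruction of binary olfactory-epithelium states by
    parsimony (ACCTRAN, DELTRAN, DOWNPASS) and maximum likelihood (two-state
    F81-type model with MAP and MPPA selection); and phylogenetic comparative
    statistics (Pagel's lambda, PGLS under BM/OU/lambda models, phylogenetic
    logistic regression, rank-sum tests). A synthetic-data module generates
    genomes with implanted OR loci, gene-family histories, and trait data with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
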