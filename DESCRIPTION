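Package: polyconflict
Title: Gene-Tree Discordance, Introgression and Paleopolyploidy Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting phylogenomic conflict in multi-species
    transcriptome data sets: curation of multi-copy gene trees (orthogroup
    copy-number filters, long-branch pruning, rooted-tree ortholog
    extraction), a multispecies-coalescent simulation test for whether
    incomplete lineage sorting can explain cytonuclear discordance, quartet
    concordance-factor hypothesis tests (T1/T3) with simplex coordinates and
    rejected-quartet mapping, ABBA-BABA D-statistic batteries with bootstrap
    significance and Holm-Bonferroni correction, LCA duplication-loss
    reconciliation with ladder-based shared-duplication (MAPS-style)
    profiling, multilabeled (MUL) tree reconciliation to distinguish allo-
    from autopolyploidy, and NG86 Ks estimation with Gaussian-mixture peak
    detection. Includes coalescent, gene-family birth-death (with optional
    whole-genome duplication) and sequence simulators that carry known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
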