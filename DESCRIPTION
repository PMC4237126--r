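Package: phylogrid
Title: Grid-Based Comparative Phylogeography of Organellar Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogeography of non-recombining
    (chloroplast or mitochondrial) sequence data across co-distributed
    species. Collapses aligned sequences into haplotypes with simple indel
    coding, builds minimum-spanning and median-joining haplotype networks,
    computes grid-based diversity (effective number of haplotypes, gene
    diversity, ordered-allele diversity), haplotype endemism and
    phylogenetic distinctiveness, tests for phylogeographic signal
    (NST > GST) by permutation, and evaluates cross-species congruence of
    spatial genetic patterns with correlation, ANOVA and Mantel tests. A
    scenario-based simulator (panmixia, refugia, range expansion,
    secondary contact) generates georeferenced synthetic data sets for
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
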