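Package: hapflow
Title: Haplotype Extraction, Distances, Trees and Networks from One Aligned FASTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-input mitochondrial DNA workflow: starting from one aligned
    multi-sequence FASTA file whose record labels encode population membership,
    hapflow collapses identical sequences into haplotypes, tabulates variable
    sites in dot notation, builds per-population and per-group haplotype
    frequency matrices, computes Hamming and Kimura two-parameter (K80)
    pairwise distance matrices, estimates neighbor-joining trees with
    nonparametric bootstrap support, constructs minimum-spanning haplotype
    networks with equal-cost alternative links, and renders the accompanying
    figures (alignment panel, clustered heatmap, haplotype networks with pie
    compositions and mutation ticks, rectangular and circular trees colored by
    population, branch length or bootstrap support). Tabular results are
    tibbles; trees are 'ape' "phylo" objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
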