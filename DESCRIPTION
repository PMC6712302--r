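Package: hgtscan
Title: Screening for Lineage-Specific Gene Content and Horizontally
    Transferred Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for inferring lineage-specific
    gene and Pfam-domain gains and losses in a recipient clade (motivated by
    the anaerobic gut fungi, Neocallimastigomycota, against their chytrid
    relatives) and for screening candidate horizontally transferred loci.
    Provides Markov clustering of all-vs-all protein similarity graphs,
    dereplication of redundant transcript variants, per-taxon domain
    copy-number matrices with shared/unique/lost/enriched classification,
    domain-architecture fusion detection, a group-wise best-hit alien
    similarity filter with Borda rank combination, gene-tree monophyly and
    sister-lineage donor diagnostics, per-site likelihoods by Felsenstein
    pruning, an approximately unbiased (AU) topology test via multiscale RELL
    bootstrap, and a synthetic-data generator with a known truth ledger that
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
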