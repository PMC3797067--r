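Package: mitofounder
Title: Mitochondrial DNA Haplogroup Classification and Rho-Statistic
    Founder Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial DNA
    control-region and whole-molecule haplotypes reported in rCRS-relative
    variant notation. Parses and validates variant tokens and haplogroup
    motifs, masks mutational hotspots, classifies haplotypes against a
    diagnostic-variant haplogroup tree, runs range-aware motif searches in
    haplotype databases, builds rooted maximum-parsimony haplotype trees,
    estimates clade founder ages with the rho statistic and its heuristic
    standard error converted through a corrected molecular clock, summarises
    haplogroup frequencies, diversity and maternal-ancestry partitions, and
    simulates star and coalescent genealogies and mixed haplotype databases
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
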