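Package: sednet
Title: Rare-Biosphere Partitioning and Co-Occurrence Networks for Sediment Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of amplicon sequence variant (ASV) tables from
    sediment microbial communities: rarefaction and alpha diversity (Shannon,
    Gini-Simpson, Chao1, ACE, Good's coverage), six-way partitioning of ASVs
    into abundant/rare/moderate categories from per-sample relative abundances,
    Spearman co-occurrence network construction with modularity-based module
    detection, within/among-module connectivity (Zi-Pi) topological roles and
    keystone-taxon extraction, trophic state index computation, and Spearman
    screening of diversity, taxa and keystones against environmental variables.
    Includes a synthetic community generator with planted ground truth (species
    abundance distribution, correlation modules, hubs/connectors, environmental
    associations) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
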