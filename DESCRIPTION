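Package: rhizolink
Title: Rhizosphere Microbiome Diversity and Metabolite Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rhizosphere microbial community surveys:
    alpha-diversity estimation (Shannon, Simpson dominance, Chao1, ACE,
    Good's coverage), community aggregation and sample pooling, Bray-Curtis,
    Jaccard and UniFrac distances with UPGMA clustering, a DCA gradient-length
    gate followed by redundancy analysis against soil environmental factors,
    pairwise taxon co-occurrence networks, and grey relational analysis (Deng
    coefficients) ranking taxa by the closeness of their abundance profiles to
    a measured compound concentration. Includes a synthetic community
    generator with planted environmental drivers and compound-tracking taxa,
    and ships the genus abundance and soil property tables of a Zanthoxylum
    nitidum rhizosphere survey as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
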