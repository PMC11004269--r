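Package: coonet
Title: Cross-Domain Microbial Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing cross-domain (bacterial-fungal)
    co-occurrence networks from amplicon sequence variant (ASV) count tables.
    Provides abundance/prevalence filtering, Spearman-correlation edge
    inference with significance thresholds, a network topology panel (edge
    density, average degree, path length, Freeman centralizations), spectral
    stability measures (natural connectivity, robustness under random node
    removal), Guimera-Amaral Zi-Pi node-role classification of keystone taxa,
    alpha/beta diversity statistics (ACE, Gini-Simpson, rarefaction,
    Bray-Curtis, ANOSIM), treatment-effect summaries (one-way ANOVA with LSD
    compact letter displays, Pearson correlation panels) and LMG relative
    importance decomposition. Includes a synthetic-community generator with
    planted correlation modules and hub taxa so the full pipeline can be
    exercised and validated without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
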