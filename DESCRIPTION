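Package: salinet
Title: Co-Occurrence Network Analysis of Microbial Communities Along
    Salinity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how microbial co-occurrence networks respond to
    increasing salinity stress along freshwater-to-seawater transects. The
    package covers the full analysis chain: rarefaction, abundant/rare
    biosphere classification and salinity-ordered grouping of samples;
    environmental-gradient statistics (Mantel tests, alpha-diversity and
    composition trends); random-forest biomarker discovery with
    cross-validated biomarker-count selection; per-group co-occurrence
    network construction from centred log-ratio transformed abundances with
    a uniform correlation threshold; network topology, modularity and
    power-law degree fits; stability under random node removal measured by
    average degree and natural connectivity; turnover of network communities
    and its decomposition by abundance class; and the relative-degree index
    with Freeman's theta effect size contrasting the roles of the abundant
    and rare biospheres. A synthetic gradient community generator with
    Gaussian niche responses, hyperdominant abundance structure and
    module-structured associations makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    randomForest,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
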