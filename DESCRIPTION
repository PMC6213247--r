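Package: dietredox
Title: Redox Proteomics and Lipid Profiling of Diet-Intervention Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent diet-intervention studies of hepatic
    oxidative stress (standard chow vs high-fat high-sucrose vs fish-oil
    supplemented). Computes fatty-acid profile summaries and desaturase
    (product/substrate) indexes from GC-FID percentage profiles, normalized
    protein carbonylation indexes (FTSC/Coomassie) from 1-D and 2-D gel
    densitometry with parts-per-million normalization and a detection-limit
    regime for low-abundance spots, biometric and redox ratio indexes, an
    assumption-routed three-group comparison engine (one-way ANOVA or
    Kruskal-Wallis with Fisher LSD or rank-based post-hoc tests and
    star/arrow significance annotation), gene-ontology facet tallies and
    interaction-network summaries, and a seeded synthetic-cohort generator
    that emulates per-animal data from published group means and standard
    deviations so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
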