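Package: dswmpnet
Title: Network Pharmacology of Plasma Metabolic Biomarkers
Version: 0.1.0
Authors@R: person("Analysis", "Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for network-pharmacology analysis of clinical plasma
    metabolomics panels. Builds bipartite metabolic-biomarker/enzyme (MEI)
    and biomarker/target (MTI) interaction networks, applies a docking-score
    (pKd) threshold to biomarker-target affinity matrices, classifies
    targets by physiological-system membership (nervous, immune,
    endocrine), and ranks KEGG-style pathways with a docking
    score-weighted multiple pharmacology index (DSWMP). Includes a
    synthetic study generator that emulates the statistical structure of
    such data sets, exact-shape bipartite fixture generators, and an
    end-to-end pipeline with SIF, GraphML, TSV and JSON exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
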