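Package: mtorwalk
Title: Network-Aware Prioritization of mTOR-Axis Genes Across Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pan-cancer, network-aware framework for prioritizing genes of
    the mTOR signaling axis. Computes per-cohort alteration prevalences and
    tissue-specificity metrics (normalized Shannon entropy and the tau index),
    scores expression-based pathway module activity as mean z-scores, runs
    degree-normalized random walk with restart (personalized PageRank) on a
    confidence-filtered protein-protein interaction network to nominate
    non-mutated, network-proximal candidates, and tests pairwise mutual
    exclusivity and co-occurrence of somatic alterations. Ships a synthetic
    cohort and network generator with planted ground truth so every stage is
    testable without access to controlled tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lmtest,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
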