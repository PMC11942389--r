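Package: herbnet
Title: Component-Target Network Contribution Index and Metabolomics
    Screening for Herb Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for network-pharmacology analysis of two-herb formulas
    and cell metabolomics. Filters candidate compounds by oral
    bioavailability and drug-likeness, builds the bipartite
    component-target network, and ranks compounds by a degree-based
    network contribution index with cumulative top-k reporting. Provides
    a Wilcoxon rank-sum differential-expression screen with log2
    fold-change thresholds, and a from-scratch metabolomics workflow:
    NIPALS PLS-DA and OPLS-DA with S-plot coordinates, VIP scores,
    venetian-blind Q2 cross-validation, permutation validation, Welch
    t-test/fold-change screening, hierarchical-clustering heatmap
    ordering, and hypergeometric pathway over-representation. Seeded
    synthetic-data generators (negative-binomial counts, planted-core
    bipartite networks, log-normal metabolite intensities) make the full
    pipeline testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
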