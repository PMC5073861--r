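Package: degmine
Title: Drug-Effect Graphs for Adverse Drug Event Mining from Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection with bipartite
    drug-effect graphs (DEGs). Builds a DEG from a SIDER-style drug/side-effect
    relationship table and a second DEG from user tweet timelines via
    dictionary-based entity extraction, an experiential-tweet random-forest
    filter and a temporal co-occurrence window; computes topological link
    features (common neighbours, Jaccard, Adamic-Adar, preferential
    attachment), sentiment and LDA topic context features; classifies edges as
    adverse versus pseudo-non-adverse with a 10-tree random forest; and
    enumerates and classifies hypothetical unrepresented adverse-drug-event
    edges. Includes seeded synthetic generators (planted-block SIDER-like
    graphs, tweet streams with a ground-truth edge ledger) used as the test
    bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
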