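Package: herbnet
Title: Network Pharmacology Target Prediction and Hub Screening for
    Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers putative protein targets for the compounds of a
    multi-herb formula by correlating chemical-similarity profiles
    against network-proximity profiles over a reference drug panel
    (drugCIPHER-CS-style scoring), builds the interaction network of
    putative and known disease targets, screens hubs and major hubs by
    four topological features (degree, node betweenness, closeness,
    k-core index) with median thresholds, intersects major hubs with
    putative targets to obtain candidate targets, and tests candidate
    sets for pathway over-representation with a Bonferroni-corrected
    hypergeometric test. Includes a fully seeded synthetic-data
    generator with planted compound-target ground truth so the whole
    chain is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
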