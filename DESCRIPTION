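Package: gpsnet
Title: Network-Based Disease Module Identification and In Silico Drug
    Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cancer-type-specific disease modules by smoothing
    length-normalized somatic mutation scores over a protein-protein
    interactome with a random walk with restart, growing candidate modules
    on a co-expression-filtered interaction network under connectivity,
    co-expression and score-gain criteria, and aggregating high-confidence
    genes into a final connected module.  Repurposes drugs against modules
    via degree-preserving network-proximity z-scores and amplitude-based
    drug-signature enrichment.  Includes seeded synthetic-data generators
    with planted ground truth, permutation validation statistics, and a
    command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
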