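Package: momarules
Title: Multi-Omics Association Rule Mining with Network-Derived Dynamic
    Thresholds and TOPSIS Ranking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mines directional association rules from paired gene-expression
    and DNA-methylation profiles of two-group studies.  Genes that are both
    differentially expressed and differentially methylated are discretized
    into directional items ("GENE+" for up-regulated and hypo-methylated,
    "GENE-" for down-regulated and hyper-methylated), frequent gene sets are
    mined with FP-growth, and per-gene-set support, confidence and lift
    cutoffs are derived dynamically from weighted shortest distances on a
    protein-protein-interaction-masked co-expression/co-methylation network.
    Surviving rules are ranked by the TOPSIS multi-criteria procedure on
    support, confidence, lift and average network distance.  Includes a
    synthetic paired-omics generator with planted modules, a nearest
    shrunken centroid rule evaluator with repeated stratified
    cross-validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
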