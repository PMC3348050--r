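Package: drugcombnet
Title: Network Analysis of Drug Combinations over Genetic Interaction Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study effective drug combinations in the context of a
    genetic interaction network and pathway gene sets. Computes the effect
    radius of a combination (mean shortest-path distance between the targets
    of its component drugs), classifies the pathway pairs targeted by
    combination partners as identical, cross-talking, interacting or
    parallel, builds a drug cocktail network from effective combinations,
    generates a degree-preserving random-combination null ensemble, and
    compares real combinations against the null with Wilcoxon rank-sum
    tests. Includes a synthetic-data generator with plantable signal so the
    whole pipeline can be exercised and calibrated without external
    databases.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
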