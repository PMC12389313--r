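Package: grdc
Title: Greedy Recommendation of Low-Risk Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines frequent 1-4 drug combinations from hospitalization
    prescription records, scores drug-drug interaction risk from molecular
    docking affinity and RMSD summaries, aggregates pairwise risk labels
    into combination-level severity classes, builds a risk-annotated
    bipartite drug-gene interaction network, and greedily ranks low-risk
    substitute drugs by a weighted combination of co-prescription
    frequency, target-gene overlap, and interaction-risk penalty. Includes
    seeded synthetic-data generators for every input (prescriptions,
    drug-gene maps, risk tables, docking mode tables) and a top-k
    recommender evaluation harness (precision, recall, F1, hit rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
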