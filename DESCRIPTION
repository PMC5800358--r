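Package: hgtrecon
Title: Time-Consistent Reconciliation of Event-Labeled Gene Trees with
    Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles rooted event-labeled gene trees (speciation,
    duplication, horizontal gene transfer) with rooted species trees.
    Implements observability checks on event-labeled gene trees, the
    lca-reconciliation map, validation of reconciliation maps, the
    auxiliary-graph characterization of time-consistency (a reconciliation
    is time-consistent exactly when a small directed constraint graph is
    acyclic), constructive synthesis of time maps and relocation of
    duplication/transfer vertices, and the equivalence with classical
    DTL-scenarios on binary trees. Ships a scenario simulator and an
    exhaustive small-instance enumerator so that every result can be
    checked against brute force, and a command-line interface for
    reconciling Newick/NHX input files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
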