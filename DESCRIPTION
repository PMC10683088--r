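Package: stratcheck
Title: Verification of Rule Strategies Attached to Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for verifying and repairing rule bases ("strategies") that
    extend biomedical ontologies in clinical decision-support systems. A
    dependency graph between inference statements is extracted from two
    confidence-scored analyses (conclusion-premise and conclusion-conclusion),
    statements are grouped by arc signatures, and the groups are used to detect
    and resolve redundancy (equivalence, subsumption, transitivity), directed
    cycles (with fake-cycle classification by forward chaining on generated
    witnesses), strong and probable conflicts, inaccessible statements and
    illegal property values. Findings persist in an anomalies knowledge base so
    expert verdicts survive re-runs. A synthetic case generator with labelled
    injected anomalies supports precision/recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
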