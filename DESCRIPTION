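Package: pathwayDR
Title: Pathway Deregulation Scoring and Database-Driven Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores per-sample pathway deregulation with a control-anchored
    principal-curve method (a Pathifier-style Pathway Deregulation Score),
    finds consensus deregulated pathways per tumor subtype across two
    expression platforms, joins them to druggable differentially expressed
    targets, classifies each drug's expected effect on the target
    (homeostasis versus anti-homeostasis), and emits per-patient drug
    recommendations. Ships a synthetic-data generator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
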