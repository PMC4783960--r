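Package: apopnet
Title: Naive Bayes Integration for Apoptotic Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions by combining heterogeneous
    evidence (smallest shared biological process, domain-domain interactions,
    gene co-expression, cross-species interolog mapping) with naive Bayesian
    likelihood-ratio integration trained on gold-standard positive and negative
    interaction sets. Includes ROC/AUC evaluation on a held-out standard test
    set, assembly of the predicted network with degree-based hub identification
    under apoptosis-specific criteria, permutation-based significance analysis
    of microarrays (SAM) with delta tuning to a target false discovery rate,
    and consensus intersection of per-tool miRNA target predictions. A seeded
    synthetic-data generator emulates every external resource with embedded
    ground truth so the full inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
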