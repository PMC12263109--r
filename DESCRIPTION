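Package: priorank
Title: Phenotype-Driven Candidate Gene Prioritization with Black-Box Scorers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks a rare-disease patient's candidate genes against clinical
    phenotype terms from the Human Phenotype Ontology using a pluggable
    black-box scorer (for example a large language model). Implements
    variant-level candidate-set construction, prompt building and response
    parsing, token log-likelihood-ratio ranking, a divide-and-conquer
    partition/score/average aggregation strategy that mitigates positional
    and literature biases, phenotype-specificity case classification
    (multi-agent and dataset specificity index), causal-gene capture-curve
    evaluation with bias diagnostics, and a synthetic-cohort simulator with
    a deterministic bias-injectable scorer so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
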