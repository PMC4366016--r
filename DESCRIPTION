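Package: ontosieve
Title: Case-Sensitivity and Information-Gain Aware Ontology Concept Recognition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dictionary-based concept recognition toolkit for biomedical
    ontologies. Parses OBO flat-file lexicons into entity profiles, assesses
    whether an ontology requires case-sensitive processing via a distributional
    case-sensitivity statistic, weighs label tokens with a divergence-from-
    randomness information-gain model combined with pointwise mutual information
    over bigrams, generates alternative term labels that omit uninformative
    tokens, indexes lexical representations in a positional concept-token vector
    space, annotates free text by exact-boundary matching, and evaluates
    annotations against gold standoff files with precision/recall/F1. Includes a
    seeded synthetic ontology and corpus generator so the full pipeline is
    testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
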