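Package: minnut
Title: Exhaustive Minimal Nutrient Set Prediction from Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes all minimal nutrient sets of a stoichiometric metabolic
    model under an exact disjunctive linear-constraint definition of growth
    (the machinery-duplicating model), using exact rational arithmetic for
    constraint satisfiability and binary decision diagrams to enumerate the
    prime implicants of the monotone growth oracle. Includes generic-reaction
    instantiation over a compound ontology, Impossible/Useless model
    simplification, lossless equivalence-class compression of the resulting
    collections, and scoring of predictions against phenotype-microarray
    growth calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
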