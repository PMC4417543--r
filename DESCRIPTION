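Package: termforge
Title: Template-Driven Ontology Class Generation with EL Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for pattern-based creation of new ontology
    classes in OBO-format ontologies such as the Gene Ontology. Provides an
    OBO 1.4 reader/writer with genus-differentia logical definitions, a
    structural OWL 2 EL reasoner (normalization, completion-rule saturation,
    classification, and incremental placement of hypothetical classes),
    declarative class-generation templates with reasoner-validated input
    fields, subset-restricted label/synonym autocompletion, free-form class
    requests with similar-label collision warnings, a persistent review queue
    with permanent identifier allocation, and per-request commits back to the
    ontology file. A command-line interface wires the pieces together for
    biocuration request workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
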