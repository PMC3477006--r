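Package: oborel
Title: Typed Validation, Kind Inference and Lint for OBO Relation Ontology Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An executable model of the OBO Relation Ontology typing
    discipline for biomedical ontologies. Ontology fragments in the OBO
    flat file format are loaded into a typed graph in which every entity
    class carries a kind drawn from the continuant/process lattice
    (process, continuant, material, immaterial). A constraint engine
    checks every relation assertion against the per-relation endpoint
    rules of the Relation Ontology (e.g. has_agent connects a process to
    a material continuant), a fixpoint inference engine refines missing
    kinds and detects unsatisfiable concepts, and lint rules flag common
    ontology defects such as multiple inheritance and relation-embedded
    term names. Includes worked ontology fragments (PRotein Ontology,
    Xenopus developmental stages, Gene Ontology), a random-model
    generator with planted violations, Graphviz DOT export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
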