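Package: codamlr
Title: Context-Oriented Directed Association Markup Language for Biological Knowledge Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A typed data model and XML dialect (CODA-ML) for context-annotated
    biological knowledge units: subject-predicate-object triples carrying
    molecular specifications (molecule type, isoform, modifications),
    hierarchical anatomical contexts (organ/tissue/cell) per entity,
    environmental contexts, provenance references and evidence scores.
    Provides a controlled 11-term predicate vocabulary with a generalization
    hierarchy and contradiction semantics, canonical byte-stable XML
    serialization with schema validation, a multi-model integration engine
    that deduplicates units and flags context-identical contradictory
    associations, conversion to and from a declared BioPAX Level-3 subset
    and SIF, packaged worked-example models, and a seeded synthetic-corpus
    generator with planted ground truth for testing integration at scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports: xml2, yaml, igraph, utils, stats
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'vocab.R'
    'core-model.R'
    'xml-io.R'
    'validate.R'
    'integration.R'
    'interop.R'
    'fixtures.R'
    'generator.R'
    'zzz.R'
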