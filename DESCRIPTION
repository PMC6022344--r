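Package: famground
Title: Grounding and Relationship Resolution for Protein Family and Complex Ontologies
Version: 0.1.0
Authors@R:
    person("famground", "developers", email = "famground@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and using a curated lexical and
    ontological resource of human protein families and complexes for biomedical
    text mining. Reads and writes the five-file tabular resource format
    (entities, isa/partof relations, grounding map, cross-database
    equivalences, gene/protein affixes), exports and parses OBO, resolves
    multi-level family/complex hierarchies into gene members, grounds entity
    strings with case-sensitive affix stripping and polarity semantics,
    proposes cross-ontology equivalences by member-set comparison and synonym
    candidates by edit distance, and computes grounding-evaluation statistics
    (category accuracy with binomial standard errors, cumulative ungrounded
    occurrence curves, event coverage, grounding-level distributions).
    Includes deterministic fixtures and seeded synthetic ontology/corpus
    generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
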