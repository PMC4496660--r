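Package: foodont
Title: Ontology-Based Food Intolerance Scoring and Allergy Rule Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for safe food consumption. Matches a consumer's
    intolerance concepts against a product's ingredient list through a food
    ontology: terms are semantically enhanced along synonym, group and is-a
    links, every consumer/product concept pair is classified into one of four
    match degrees (Exact, Plugin, Subsume, Dissimilar), pair contributions are
    weighted by subsumption-hierarchy distance, and the contributions are
    aggregated into an intolerance score with a modified Jaro-Winkler factor,
    an integer intolerance percentage and a red/yellow/green verdict. A
    DL-safe forward-chaining rule engine infers allergy-risk facts from
    SWRL-style rules, with ontology-backed expansion of rule concepts so
    synonyms and subclasses of an allergen also trigger its rule. Includes
    readers for a small OWL/XML dialect and a structured fixture format, a
    seeded synthetic-ontology generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
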