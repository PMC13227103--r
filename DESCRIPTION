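Package: rosettastmt
Title: Rosetta Statements: FAIR Knowledge-Graph Construction from Simple
    Sentences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model natural-language statements as reified n-ary RDF
    following the Rosetta Statement approach: statement-type schemata
    mirroring the predicate-argument structure of simple English
    sentences, a light RDF dialect (numbered position properties) and a
    full dialect with anchors, versions, per-position edit history and
    soft delete, dynamic-label sentence rendering and mind-map patterns,
    SHACL shape generation and validation, nanopublication export,
    declarative schema cross-walks (OBI- and OBOE-style measurement
    graphs, table rows), and slot-form SPARQL query generation, plus a
    seeded synthetic statement-corpus generator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
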