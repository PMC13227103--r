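# rosettastmt

Knowledge graphs built by and for domain experts fail at a predictable
point: the schemata. Observation-centric measurement models (OBI, OBOE)
route a single sentence's worth of information — *"This apple has a weight
of 241.68 grams"* — through intermediate nodes like *scalar value
specification* or *observation* that mean nothing to the person entering or
reading the data, and every new statement type brings its own properties
and modelling idiosyncrasies. `rosettastmt` implements the **Rosetta
Statement** approach for R: every statement type mirrors the
predicate–argument structure of one simple English sentence, every token
statement is a reified n-ary resource with its own IRI, and a small fixed
property vocabulary is shared by all types. The audience is biocurators and
FAIR-data engineers who need to capture instance-level assertions quickly,
render them back as sentences, validate them mechanically, and exchange
them with observation-centric schemata when reasoning-capable targets are
required.

## The model

A **statement type** is a class defined by a verb (e.g. *has weight*,
*travels*) together with a subject position and an ordered list of object
positions. Each position carries a thematic role label (QUALITY, UNIT,
DESTINATION_LOCATION, …), a required/optional flag (argument vs adjunct), a
cardinality, and a constraint — an ontology class for resource slots, an
XSD datatype (optionally with pattern or numeric range) for literal slots.

Two RDF dialects serialize a token statement *s* of type *T*:

* **light** — `s rdf:type T`, one `rosetta:subject` triple per subject, and
  per object binding one triple with a sequentially numbered property from
  the families `rosetta:{required|optional}[Literal]ObjectPosition<i>`. The
  basic weight measurement needs **3** slot triples where the OBI and OBOE
  renderings of the same content need 6 and 5.
* **full** — a version-independent **anchor** resource linked via
  `rosetta:hasVersion` to statement versions; each version reaches its
  subjects and objects only indirectly through **position instances**
  (one IRI per bound value, carrying `rosetta:order`, `rosetta:value`,
  display text and boolean logical annotations such as `rosetta:transitive`).
  Updates append versions; deletion is soft (`rosetta:deletedAt/By`), so
  metadata stays accessible after the data are withdrawn (FAIR A2), and the
  anchor always resolves to the highest-numbered non-deleted version.

Around the core model the package provides dynamic-label sentence
rendering and mind-map patterns, SHACL shape generation + validation (the
shape IRI is the schema IRI, so `rosetta:hasDataSchema` resolves to the
shape the graph must conform to), nanopublication export (head /
assertion / provenance / publication-info named graphs), declarative schema
cross-walks (OBI-style, OBOE-style, table rows, custom node/edge
templates), slot-form SPARQL generation with an in-package evaluator and
facet counts, and a seeded synthetic-corpus generator. Serialization:
Turtle, TriG, N-Quads, JSON-LD; no blank nodes anywhere, so output is
canonical and diff-stable.

## Worked example

```r
library(rosettastmt)
set.seed(1)

schemas <- rosetta_fixture_schemas()
sts     <- rosetta_paper_statements(schemas)

# light dialect: the whole measurement in three slot triples
g <- to_light_graph(sts$weight_basic, schemas$weight)
count_slot_triples(g, sts$weight_basic$statement_iri)
#> [1] 3

# the same content pushed through the OBI-style cross-walk needs six
obi <- apply_crosswalk(sts$weight_basic, crosswalk_obi(schemas$weight),
                       schemas$weight)
count_crosswalk_triples(obi)
#> [1] 6

# dynamic label: slots + pre/post texts -> a sentence
tpl <- derive_label_template(schemas$measurement)
render_label(tpl, sts$measurement_fig1, schemas$measurement)
#> [1] "This apple has a weight of 241.68 grams (95% conf. interval: 241.31–242.05 grams)"

# empty optional slots vanish together with their texts
render_label(tpl, sts$measurement_orange, schemas$measurement)
#> [1] "This orange has a weight of 114.21 grams"

# full dialect: append-only versioning with per-position history
a <- create_anchor(sts$weight_basic, schemas$weight)
a <- update_statement(a, list(VALUE = typed_literal("242.00", "float")),
                      editor = "curator-2")
resolve_current(a)$version_number
#> [1] 2
position_history(a, "VALUE")$changed
#> [1] FALSE  TRUE

# every statement version is publishable as a nanopublication
length(nanopub_graphs(export_nanopub(a)))
#> [1] 4
```

The first count is the light dialect's triple economy: subject, value and
unit — nothing else. The rendered sentences come verbatim from the stored
lexical forms (no numeric reformatting), with the confidence-interval
parenthetical dropping out as one unit when its slots are empty. The
version history records who changed which position when, and the
four-graph nanopublication separates the assertion from metadata about the
assertion and metadata about the publication itself.

A command-line interface wraps the same functions
(`rosetta stmt render --fixture measurement_fig1`,
`rosetta shape validate --schema s.json --data g.ttl`,
`rosetta fixtures make --seed 42 --n 10 --out dir`); see `exec/rosetta`.

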