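---
title: "Modelling statements, not reality: methods behind rosettastmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling statements, not reality: methods behind rosettastmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettastmt)
set.seed(1)
```

## The modelling stance

Most semantic data schemata try to model a mind-independent reality: a
weight measurement becomes an observation event with a measurement datum
and a value specification, each a node of its own. `rosettastmt` takes the
opposite stance: it models the *statement* — the simple English sentence a
domain expert would write — and reifies it as a single resource with one
slot per syntactic position. The assumptions this buys and costs:

* every captured assertion is expressible as one simple sentence (one verb,
  one subject phrase, object phrases); complex narratives, procedures and
  conditionals are out of scope;
* slots carry the semantics through their thematic role and constraint, so
  no per-type property vocabulary is needed — all types share a small fixed
  set of properties, which is what makes generic tooling (form-based query
  generation, facets, uniform SHACL shapes) possible;
* the graph is *not* reasoning-capable; reasoning-capable targets are
  reached by cross-walks, not by the statement model itself.

## Statement types and their invariants

A type is defined by `define_statement_type()`: a verb label, a subject
position with a resource constraint, and ordered object positions, each
with a role label (unique per schema), required flag (argument vs
adjunct), cardinality (`max_values`), and a constraint — an ontology class
for resource slots, one of the editor datatypes (`text`, `URL`, `date`,
`datetime`, `boolean`, `integer`, `decimal`, `float`, mapped onto XSD) for
literal slots, optionally with a regex pattern or a numeric range.
`validate_type_schema()` returns violations as data; the generator and the
validator are kept consistent by a property test over randomized schemata.

Zero object positions are allowed: intransitive verbs ("PERSON sleeps")
are legitimate statements and nothing in the metamodel forbids them.

One rule is stricter than it may first appear: a position (and the subject)
may not bind the same value twice. RDF triples form a set, so a duplicate
value would be silently collapsed by any serialization, breaking the
count and round-trip invariants; rejecting duplicates at creation time
makes the unrepresentability explicit instead of silent.

## The two RDF dialects

**Light.** The statement instance links directly to its values via
numbered properties from four families (required/optional ×
resource/literal). A single index sequence — the position's schema index —
is shared across the families; the figures in the source material number
the properties but never state the rule across mixed kinds, so one shared
sequence is used and documented here. The light dialect has no order
property: when a position holds several values, parsing assigns order
ranks by lexicographic sort of the serialized value, which is
deterministic but not order-preserving. Lossless ordering requires the
full dialect; the round-trip property for the light dialect is therefore
stated *up to value order*. Display texts (a date shown as "21st of April
2023" next to its typed value) ride on a companion `...Display` property
and are limited to single-valued positions in this dialect, since nothing
could pair texts with values otherwise.

**Full.** An anchor owns the version chain; each version reaches its
values only through position instances. The package mints *one position
instance per bound value* rather than one per position: per-value order
ranks and display texts must attach somewhere, and when the value is a
literal there is no other node to attach them to. The R-level
`PositionInstance` view still groups a position's ordered bindings.
Version-level metadata (editor, timestamp, certainty, version number,
optional external identifier such as a DOI) lives on the version; creator,
import source, modifiability and soft-delete markers live on the anchor —
the source material lists both sets with overlap, and single ownership
keeps every triple's provenance unambiguous. Updates re-validate against
the schema and append; nothing ever rewrites an earlier version's
subgraph, which is what makes the "old graph is a subgraph of the new
graph" property testable at the triple level. Soft delete only ever adds
`deletedAt`/`deletedBy` triples. Deleting individual versions is
supported, and an anchor whose versions are all deleted is distinguishable
(different error condition) from a deleted anchor.

Certainty is carried as a decimal in [0, 1]; the source material never
fixes a value space, and a unit interval composes with probabilistic
downstream use. The vocabulary namespace itself
(`https://w3id.org/rosetta/` by default) is provisional and configurable
via `options(rosettastmt.base_iri = ...)`, because the canonical ontology
IRIs are not reproduced in the text the package was built from. Instance
IRIs are UUIDv4-based from R's RNG (reproducible under `set.seed()`),
type IRIs are slugged from labels, and there are no blank nodes anywhere —
stable node identity is what makes version diffs and canonical
serialization possible.

## Rendering

`derive_label_template()` produces the canonical template — subject slot,
verb, object slots in index order, each with its pre/post texts — unless
the schema declares its own templates, in which case the first declared
one is the default. Declared templates may repeat a slot and may group
segments: the measurement-with-CI template mentions UNIT twice ("…of
MAIN_VALUE UNIT (… LOWER_VALUE–UPPER_VALUE UNIT)"), and the whole
parenthetical is one group that disappears when any of its slots is
empty. Canonical derivation never repeats a role.

Literals render by stored lexical form verbatim — never through numeric
reformatting — so "241.68" reproduces exactly; multi-valued positions join
with a serial comma ("Osnabrück, Hengelo, Utrecht, and Rotterdam"); the
confidence-interval range uses an en dash (U+2013). Negation rendering is
unspecified in the source material; the package prefixes "It is not the
case that ", which is verbose but unambiguous and composes with any
template. Token gluing removes spaces around parentheses, before `%`, `,`,
`:` and around the en dash, so templates can be written with natural word
tokens.

```{r}
schemas <- rosetta_fixture_schemas()
sts <- rosetta_paper_statements(schemas)
tpl <- derive_label_template(schemas$measurement)
render_label(tpl, sts$measurement_fig1, schemas$measurement)
render_label(tpl, sts$measurement_orange, schemas$measurement)
```

## Shapes

`generate_shape()` emits one SHACL node shape per type and dialect, with
the schema IRI as the shape IRI so that `rosetta:hasDataSchema` resolves
to the shape. Required positions become minCount 1, finite cardinalities
maxCount, literal constraints sh:datatype (+ pattern/range), resource
constraints sh:class with sh:nodeKind. Full-dialect shapes target the
objects of `rosetta:hasVersion` and constrain position instances through
qualified value shapes. Validation is implemented in the package over the
in-memory graph; it covers exactly the SHACL core subset the generator
emits. Two deliberate choices:

* **Subclass admission without a reasoner.** A value conforms to sh:class
  if the data graph asserts its type or an `rdfs:subClassOf` chain to the
  constraint class. Hierarchies must be present in the data
  (`fixture_ontology()` ships the ones the packaged fixtures need);
  nothing is inferred.
* **Open by default.** Closed shapes would reject the forward-compatible
  addition of optional adjuncts to a type, which the metamodel explicitly
  allows; closedness is available behind a flag for curated stores.

## Nanopublications, cross-walks, queries

Each statement version exports as its own nanopublication: four named
graphs under `npIRI#head/#assertion/#provenance/#pubinfo`. The assertion
graph is the version subgraph with all metadata triples stripped; metadata
*about the assertion* (certainty, extraction method, claim author, import
source, context) goes to provenance, metadata *about the nanopublication*
(creator, timestamp, version number, external identifier) to
publication-info. The split is the package's reading of "depending on the
type of metadata"; the disjointness of assertion and metadata triples is
enforced by construction and asserted by test.

Cross-walks are declarative: intermediate nodes (minted deterministically
from the statement IRI), edges whose endpoints are nodes, roles, constants
or the subject, and an entity map for slots whose target schema constrains
the vocabulary (a general-vocabulary gram must become a UO gram for the
OBI target). The built-in OBI-style template uses the canonical datum /
value-specification chain (6 slot-path triples incl. the quality's
inheres-in link) and the OBOE-style template the observation / measurement
chain (5); the source material fixes only the pair {5, 6}, and this
assignment is the package's own, locked by tests. The basic weight
statement has no QUALITY slot — its verb already fixes the quality, which
is why it serializes to three slot triples — so the cross-walks supply the
quality as a constant node, and the tabular target still emits a quality
column alongside the dedicated statement-IRI column. Graph targets are
wrapped in a named graph whose IRI is the statement IRI, keeping the
statement referencable.

Slot queries generate SPARQL 1.1 text (full-dialect queries resolve
anchors to their current non-deleted version via NOT EXISTS filters over
version numbers) and are also evaluated in-package; tests hold the
evaluator, the generated SPARQL executed by an external engine, and a
brute-force filter over the records to identical results. Facets count
resource values by label and literal values by lexical form, per role.

## The synthetic corpus

`make_fixtures(seed, n_per_type)` is a pure function of its arguments. It
always contains the worked examples with their published values (the
241.68 g apple with CI 241.31–242.05 at 95%, the 212.45 g apple, the
Berlin–Paris train journey on 2023-04-21, the multi-city VIA variant, and
the Sarah–Bob meeting on 2021-07-04), plus `n_per_type` random statements
per type drawn from small pools: fruit weights uniform in 50–500 g,
CI half-widths 0.05–2 g (present in 60% of measurements), six persons,
seven cities, three transport modes, travel dates through 2023, 0–3 VIA
stops, occasional negation (5–10%) and certainty values. Timestamps are
fixed offsets, not wall-clock time, so equal seeds give byte-identical
serialized corpora. What the generator deliberately does *not* emulate:
malformed IRIs, heterogeneous namespaces, label languages other than
English, concurrent edit conflicts, or schema drift — passing tests show
the machinery is lossless and consistent on clean single-curator data,
not that it survives adversarial real-world graphs.

The packaged meeting type has exactly two object positions (PERSON, DATE),
the ternary verb of the worked example; a location adjunct would be a
forward-compatible extension of the type, not part of the packaged
fixture.

## Problem sizes and numerical choices

The test suite and the acceptance script run the property suites on a
corpus of 125 random statements per type (507 statements total, ~18 000
quads in full dialect), which exercises every code path in well under a
minute on one CPU; counts and round-trips are exact, so no tolerances are
involved anywhere. Canonical serialization sorts quads by (graph, subject,
predicate, object kind, object, datatype) with radix order, making
byte-level comparison meaningful. The Turtle/TriG parser accepts the
canonical subset the writers emit (one triple per line, no blank nodes);
N-Quads and expanded JSON-LD are parsed in full for the feature set the
package uses.

## Known limitations

* The light dialect cannot represent value order or per-value display
  texts on multi-valued positions (by design; use the full dialect).
* SHACL support is the generated subset, not a general validator
  (no SPARQL-based constraints, no closed-world lists).
* Cross-walk inversion requires an injective entity map and is defined for
  graph targets only.
* The store is in-memory with TriG as its persistence format; there is no
  database backend, no concurrent-editor conflict resolution (the version
  contract is strictly sequential append), and no live resolution of
  Wikidata or ontology terms — constraint classes are opaque IRIs.
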