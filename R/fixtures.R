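#' Packaged statement types and the seeded synthetic corpus
#'
#' Four statement types ship with the package -- a basic weight
#' measurement, a measurement with confidence interval, a travel statement
#' and a meeting statement -- together with their worked-example token
#' statements and a seeded generator of random statements over small entity
#' pools. Generation is a pure function of (seed, size parameters).
#' @name fixtures
NULL

WD <- function(q) paste0("http://www.wikidata.org/entity/", q)

.wd_classes <- c(
  material_entity = "Q223557",  # physical object
  apple = "Q89", orange = "Q13191", pear = "Q434",
  quality = "Q1207505", unit = "Q47574", person = "Q215627",
  transport = "Q334166", location = "Q2221906", city = "Q515")

#' The packaged statement-type schemata
#'
#' @param base namespace base IRI
#' @return named list of `rosetta_schema`: `weight`, `measurement`,
#'   `travel`, `meet`
#' @export
rosetta_fixture_schemas <- function(base = getOption("rosettastmt.base_iri",
                                                     "https://w3id.org/rosetta/")) {
  res <- function(cls) constraint_spec("resource", value_class = WD(.wd_classes[[cls]]))
  lit <- function(dt, ...) constraint_spec("literal", datatype = dt, ...)

  weight <- define_statement_type(
    label = "has weight", verb_text = "has a weight of",
    description = "Weight measurement of a material entity.",
    examples = "This apple has a weight of 241.68 grams",
    subject_spec = position_spec("MATERIAL ENTITY", res("material_entity"),
                                 pre = "This"),
    object_specs = list(
      position_spec("VALUE", lit("float"), placeholder = "weight value"),
      position_spec("UNIT", res("unit"), placeholder = "unit")),
    base = base)

  ci_template <- label_template(list(
    seg_text("This"), seg_slot("subject"), seg_verb(),
    seg_slot("QUALITY", post = "of"), seg_slot("MAIN_VALUE"),
    seg_slot("UNIT"),
    seg_text("(", group = "ci"),
    seg_slot("INTERVAL_VALUE", group = "ci"),
    seg_text("% conf. interval:", group = "ci"),
    seg_slot("LOWER_VALUE", group = "ci"),
    seg_text("–", group = "ci"),
    seg_slot("UPPER_VALUE", group = "ci"),
    seg_slot("UNIT", group = "ci"),
    seg_text(")", group = "ci")), name = "ci")
  measurement <- define_statement_type(
    label = "has measurement", verb_text = "has a",
    description = "Measurement of a quality, optionally with a confidence interval.",
    examples = paste("This apple has a weight of 241.68 grams",
                     "(95% conf. interval: 241.31–242.05 grams)"),
    subject_spec = position_spec("MATERIAL ENTITY", res("material_entity"),
                                 pre = "This"),
    object_specs = list(
      position_spec("QUALITY", res("quality"), post = "of"),
      position_spec("MAIN_VALUE", lit("float")),
      position_spec("UPPER_VALUE", lit("float"), required = FALSE),
      position_spec("LOWER_VALUE", lit("float"), required = FALSE),
      position_spec("INTERVAL_VALUE", lit("decimal", min = 0, max = 100),
                    required = FALSE),
      position_spec("UNIT", res("unit"))),
    display_templates = list(ci_template),
    base = base)

  travel <- define_statement_type(
    label = "travels", verb_text = "travels",
    description = "A person travels between locations.",
    examples = "Anna travels by train from Berlin to Paris on the 21st of April 2023",
    subject_spec = position_spec("PERSON", res("person")),
    object_specs = list(
      position_spec("TRANSPORTATION", res("transport"), pre = "by",
                    required = FALSE),
      position_spec("DEPARTURE_LOCATION", res("location"), pre = "from",
                    required = FALSE),
      position_spec("DESTINATION_LOCATION", res("location"), pre = "to"),
      position_spec("VIA", res("location"), pre = "via", required = FALSE),
      position_spec("DATETIME", lit("date"), pre = "on the",
                    required = FALSE)),
    base = base)

  meet <- define_statement_type(
    label = "met", verb_text = "met",
    description = "Two persons met on a date.",
    examples = "Sarah met Bob on 4th of July 2021",
    subject_spec = position_spec("AGENT", res("person")),
    object_specs = list(
      position_spec("PERSON", res("person")),
      position_spec("DATE", lit("date"), pre = "on")),
    base = base)

  list(weight = weight, measurement = measurement, travel = travel,
       meet = meet)
}

.pools <- list(
  fruit = list(c("apple", "Q89"), c("orange", "Q13191"), c("pear", "Q434")),
  person = c("Anna", "Bob", "Sarah", "Christopher", "Maria", "Li"),
  city = list(c("Berlin", "Q64"), c("Paris", "Q90"),
              c("Osnabrück", "Q2905"), c("Hengelo", "Q9832"),
              c("Utrecht", "Q803"), c("Rotterdam", "Q34370"),
              c("New York City", "Q60")),
  transport = list(c("train", "Q870"), c("bus", "Q5638"),
                   c("bicycle", "Q11442")))

.fx_gram <- function() resource_ref(WD("Q41803"), "grams",
                                    class_iri = WD(.wd_classes[["unit"]]))
.fx_weight <- function() resource_ref(WD("Q11423"), "weight",
                                      class_iri = WD(.wd_classes[["quality"]]))
.fx_person <- function(name)
  resource_ref(paste0("https://example.org/person/", iri_slug(name)), name,
               class_iri = WD(.wd_classes[["person"]]))
.fx_city <- function(p) resource_ref(WD(p[2]), p[1],
                                     class_iri = WD(.wd_classes[["city"]]))

.fx_meta <- function(creator = "curator-1",
                     created_at = "2024-03-01T09:00:00Z")
  provenance_metadata(creator = creator, created_at = created_at,
                      extraction_method = "manual")

#' The paper-style worked-example statements
#' @param schemas result of [rosetta_fixture_schemas()]
#' @return named list of `rosetta_statement`
#' @export
rosetta_paper_statements <- function(schemas) {
  apple <- function(n) resource_ref(paste0("https://example.org/sample/apple-", n),
                                    "apple", class_iri = WD("Q89"))
  flt <- function(x) typed_literal(x, "float")

  weight_basic <- create_statement(
    schemas$weight, apple(1),
    list(VALUE = flt("241.68"), UNIT = .fx_gram()), metadata = .fx_meta())

  measurement_fig1 <- create_statement(
    schemas$measurement, apple(1),
    list(QUALITY = .fx_weight(), MAIN_VALUE = flt("241.68"),
         UPPER_VALUE = flt("242.05"), LOWER_VALUE = flt("241.31"),
         INTERVAL_VALUE = typed_literal("95", "decimal"),
         UNIT = .fx_gram()),
    metadata = .fx_meta(), certainty = 0.95)

  measurement_intro <- create_statement(
    schemas$measurement, apple(2),
    list(QUALITY = .fx_weight(), MAIN_VALUE = flt("212.45"),
         UPPER_VALUE = flt("212.47"), LOWER_VALUE = flt("212.44"),
         INTERVAL_VALUE = typed_literal("95", "decimal"),
         UNIT = .fx_gram()),
    metadata = .fx_meta())

  measurement_orange <- create_statement(
    schemas$measurement,
    resource_ref("https://example.org/sample/orange-1", "orange",
                 class_iri = WD("Q13191")),
    list(QUALITY = .fx_weight(), MAIN_VALUE = flt("114.21"),
         UNIT = .fx_gram()), metadata = .fx_meta())

  city <- function(name) .fx_city(Filter(function(p) p[1] == name,
                                         .pools$city)[[1]])
  travel_anna <- create_statement(
    schemas$travel, .fx_person("Anna"),
    list(TRANSPORTATION = resource_ref(WD("Q870"), "train",
                                       class_iri = WD(.wd_classes[["transport"]])),
         DEPARTURE_LOCATION = city("Berlin"),
         DESTINATION_LOCATION = city("Paris"),
         DATETIME = typed_literal("2023-04-21", "date",
                                  display = "21st of April 2023")),
    metadata = .fx_meta())

  travel_via <- create_statement(
    schemas$travel, .fx_person("Anna"),
    list(TRANSPORTATION = resource_ref(WD("Q870"), "train",
                                       class_iri = WD(.wd_classes[["transport"]])),
         DEPARTURE_LOCATION = city("Berlin"),
         DESTINATION_LOCATION = city("Paris"),
         VIA = list(city("Osnabrück"), city("Hengelo"),
                    city("Utrecht"), city("Rotterdam")),
         DATETIME = typed_literal("2023-04-21", "date",
                                  display = "21st of April 2023")),
    metadata = .fx_meta())

  meet_sarah <- create_statement(
    schemas$meet, .fx_person("Sarah"),
    list(PERSON = .fx_person("Bob"),
         DATE = typed_literal("2021-07-04", "date",
                              display = "4th of July 2021")),
    metadata = .fx_meta())

  list(weight_basic = weight_basic, measurement_fig1 = measurement_fig1,
       measurement_intro = measurement_intro,
       measurement_orange = measurement_orange,
       travel_anna = travel_anna, travel_via = travel_via,
       meet_sarah = meet_sarah)
}

#' Companion ontology graph for the fixtures
#'
#' Subclass assertions and labels connecting the fixture entity classes to
#' the schemata's constraint classes (shape validation relies on subclass
#' hierarchies being asserted in the data; no reasoner runs).
#' @return a `rosetta_graph`
#' @export
fixture_ontology <- function() {
  g <- rdf_graph()
  sub <- function(child, parent)
    g <<- g_add(g, triple(WD(.wd_classes[[child]]), RDFS_SUBCLASS,
                          WD(.wd_classes[[parent]])))
  sub("apple", "material_entity"); sub("orange", "material_entity")
  sub("pear", "material_entity"); sub("city", "location")
  for (nm in names(.wd_classes))
    g <- g_add(g, lit_triple(WD(.wd_classes[[nm]]), RDFS_LABEL,
                             gsub("_", " ", nm)))
  g
}

.rand_statement <- function(type, schemas, i) {
  flt <- function(x) typed_literal(format(x, nsmall = 2), "float")
  pick <- function(pool) pool[[sample.int(length(pool), 1L)]]
  meta <- .fx_meta(creator = sample(c("curator-1", "curator-2", "bot-A"), 1L),
                   created_at = sprintf("2024-03-%02dT%02d:00:00Z",
                                        sample.int(28, 1L), sample.int(23, 1L)))
  if (type == "weight") {
    fr <- pick(.pools$fruit)
    create_statement(schemas$weight,
      resource_ref(paste0("https://example.org/sample/", fr[1], "-r", i),
                   fr[1], class_iri = WD(fr[2])),
      list(VALUE = flt(round(runif(1, 50, 500), 2)), UNIT = .fx_gram()),
      metadata = meta, negated = runif(1) < 0.05)
  } else if (type == "measurement") {
    fr <- pick(.pools$fruit)
    v <- round(runif(1, 50, 500), 2)
    w <- round(runif(1, 0.05, 2), 2)
    with_ci <- runif(1) < 0.6
    create_statement(schemas$measurement,
      resource_ref(paste0("https://example.org/sample/", fr[1], "-m", i),
                   fr[1], class_iri = WD(fr[2])),
      c(list(QUALITY = .fx_weight(), MAIN_VALUE = flt(v),
             UNIT = .fx_gram()),
        if (with_ci) list(UPPER_VALUE = flt(v + w), LOWER_VALUE = flt(v - w),
                          INTERVAL_VALUE = typed_literal("95", "decimal"))),
      metadata = meta,
      certainty = if (runif(1) < 0.5) round(runif(1, 0.5, 1), 2))
  } else if (type == "travel") {
    n_via <- sample(0:3, 1L)
    vias <- lapply(sample(.pools$city, n_via), .fx_city)
    create_statement(schemas$travel, .fx_person(sample(.pools$person, 1L)),
      c(list(DESTINATION_LOCATION = .fx_city(pick(.pools$city))),
        if (runif(1) < 0.8) list(DEPARTURE_LOCATION = .fx_city(pick(.pools$city))),
        if (runif(1) < 0.8) list(TRANSPORTATION = {
          tr <- pick(.pools$transport)
          resource_ref(WD(tr[2]), tr[1],
                       class_iri = WD(.wd_classes[["transport"]]))
        }),
        if (n_via > 0) list(VIA = vias),
        if (runif(1) < 0.7) list(DATETIME = typed_literal(
          format(as.Date("2023-01-01") + sample.int(365, 1L)), "date"))),
      metadata = meta)
  } else {
    who <- sample(.pools$person, 2L)
    create_statement(schemas$meet, .fx_person(who[1]),
      list(PERSON = .fx_person(who[2]),
           DATE = typed_literal(format(as.Date("2021-01-01") +
                                         sample.int(365, 1L)), "date")),
      metadata = meta, negated = runif(1) < 0.1)
  }
}

#' Build the fixture corpus
#'
#' Deterministic in (seed, n_per_type): the same seed yields byte-identical
#' serialized corpora. `n_per_type = 0` returns the worked examples only.
#'
#' @param seed integer RNG seed
#' @param n_per_type number of additional random statements per type
#' @param base namespace base IRI
#' @return a `rosetta_corpus`: `schemas`, `statements` (named list;
#'   `$type` key on each element), `seed`, `n_per_type`
#' @export
make_fixtures <- function(seed = 1L, n_per_type = 0L,
                          base = getOption("rosettastmt.base_iri",
                                           "https://w3id.org/rosetta/")) {
  stopifnot(n_per_type >= 0)
  set.seed(as.integer(seed))
  schemas <- rosetta_fixture_schemas(base)
  sts <- rosetta_paper_statements(schemas)
  types <- c(weight_basic = "weight", measurement_fig1 = "measurement",
             measurement_intro = "measurement",
             measurement_orange = "measurement",
             travel_anna = "travel", travel_via = "travel",
             meet_sarah = "meet")
  statements <- lapply(names(sts), function(nm)
    list(name = nm, type = types[[nm]], statement = sts[[nm]]))
  for (ty in names(schemas)) {
    for (i in seq_len(n_per_type)) {
      statements[[length(statements) + 1L]] <-
        list(name = paste0(ty, "_rand_", i), type = ty,
             statement = .rand_statement(ty, schemas, i))
    }
  }
  names(statements) <- vapply(statements, `[[`, character(1), "name")
  structure(list(schemas = schemas, statements = statements,
                 seed = as.integer(seed), n_per_type = as.integer(n_per_type)),
            class = "rosetta_corpus")
}

#' Canonical serialization of a corpus
#'
#' Concatenated canonical Turtle of every statement's light graph, in
#' corpus order; used to demonstrate generation determinism.
#' @param corpus a `rosetta_corpus`
#' @return single string
#' @export
corpus_serialize <- function(corpus) {
  paste(vapply(corpus$statements, function(e)
    write_turtle(to_light_graph(e$statement, corpus$schemas[[e$type]])),
    character(1)), collapse = "\n")
}

#' Build a statement store from a corpus
#'
#' Wraps every corpus statement in a full-dialect anchor.
#' @param corpus a `rosetta_corpus`
#' @return a `rosetta_store`
#' @export
corpus_store <- function(corpus) {
  store <- rosetta_store(schema_registry(unname(corpus$schemas)))
  for (e in corpus$statements)
    store <- store_add(store,
                       create_anchor(e$statement, corpus$schemas[[e$type]]))
  store
}

#' @export
print.rosetta_corpus <- function(x, ...) {
  cat("<rosetta_corpus> seed ", x$seed, ", ", length(x$statements),
      " statements over ", length(x$schemas), " types\n", sep = "")
  invisible(x)
}
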