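test_that("light shapes carry one property shape per position plus the subject", {
  sch <- fx_schemas()$measurement
  b <- generate_shape(sch, "light")
  expect_length(b$prop_shapes, 7L)  # subject + 6 positions
  expect_identical(b$shape_iri, sch$schema_iri)
  req <- Filter(function(p) p$role == "QUALITY", b$prop_shapes)[[1]]
  expect_identical(req$min_count, 1L)
  opt <- Filter(function(p) p$role == "UPPER_VALUE", b$prop_shapes)[[1]]
  expect_identical(opt$min_count, 0L)
  # unbounded max_values emits no maxCount
  expect_null(opt$max_count)
  txt <- write_turtle(shape_graph(b))
  expect_false(grepl("maxCount", txt))
  # a bounded position does emit one
  subj <- position_spec("SUBJ", constraint_spec("resource",
                                                value_class = wd("Q35120")))
  capped <- define_statement_type("tags",
    subject_spec = subj,
    object_specs = list(position_spec("TAG",
      constraint_spec("literal", datatype = "text"), max_values = 2)))
  expect_true(grepl("maxCount", write_turtle(shape_graph(
    generate_shape(capped, "light")))))
})

test_that("shape graphs are syntactically valid SHACL for an independent parser", {
  sch <- fx_schemas()$measurement
  for (dialect in c("light", "full")) {
    g <- shape_graph(generate_shape(sch, dialect))
    f <- tempfile(fileext = ".ttl")
    writeLines(write_turtle(g), f, sep = "")
    out <- run_python(sprintf(paste0(
      "import rdflib\n",
      "g = rdflib.Graph(); g.parse('%s', format='turtle')\n",
      "SH = rdflib.Namespace('http://www.w3.org/ns/shacl#')\n",
      "print('NODESHAPES', len(list(g.subjects(rdflib.RDF.type, SH.NodeShape))))\n",
      "print('TRIPLES', len(g))\n"), f))
    expect_true(any(grepl("NODESHAPES 1", out)), label = dialect)
    expect_true(any(grepl(paste("TRIPLES", nrow(g)), out)), label = dialect)
  }
})

test_that("graphs from valid statements conform to their generated shapes (property)", {
  set.seed(81)
  corpus <- make_fixtures(81, n_per_type = 4)
  onto <- fixture_ontology()
  reg <- corpus$schemas
  for (e in corpus$statements) {
    sch <- reg[[e$type]]
    light <- validate_statement(
      g_union(to_light_graph(e$statement, sch), onto),
      generate_shape(sch, "light"))
    expect_true(light$conforms, label = paste(e$name, "light"))
    full <- validate_statement(
      g_union(to_full_graph(create_anchor(e$statement, sch)), onto),
      generate_shape(sch, "full"))
    expect_true(full$conforms, label = paste(e$name, "full"))
  }
})

test_that("single-fault mutants each produce at least one violation", {
  set.seed(82)
  sch <- fx_schemas()$measurement
  sts <- fx_statements()
  onto <- fixture_ontology()
  bundle <- generate_shape(sch, "light")
  base <- g_union(to_light_graph(sts$measurement_fig1, sch), onto)
  vocab <- rosetta_vocabulary()
  reshape <- function(df) structure(df, prefixes = attr(base, "prefixes"),
                                    class = c("rosetta_graph", "data.frame"))
  main_pred <- position_property(vocab, TRUE, TRUE, 2)  # MAIN_VALUE
  unit_pred <- position_property(vocab, TRUE, FALSE, 6) # UNIT
  # datatype flip float -> string
  m1 <- as.data.frame(base)
  m1$datatype[m1$predicate == main_pred] <- xsd_iri("string")
  r1 <- validate_statement(reshape(m1), bundle)
  expect_false(r1$conforms)
  expect_true(any(r1$violations$rule == "datatype" &
                    r1$violations$path == main_pred))
  # dropped required triple
  m2 <- as.data.frame(base)
  m2 <- m2[m2$predicate != unit_pred, , drop = FALSE]
  r2 <- validate_statement(reshape(m2), bundle)
  expect_true(any(r2$violations$rule == "minCount" &
                    r2$violations$path == unit_pred))
  # wrong class for a resource slot
  m3 <- as.data.frame(base)
  quality_iri <- m3$object[m3$predicate == position_property(vocab, TRUE, FALSE, 1)]
  m3$object[m3$subject == quality_iri & m3$predicate == RDF_TYPE] <- wd("Q515")
  r3 <- validate_statement(reshape(m3), bundle)
  expect_true(any(r3$violations$rule == "class"))
  # out-of-range interval value
  m4 <- as.data.frame(base)
  ival_pred <- position_property(vocab, FALSE, TRUE, 5)
  m4$object[m4$predicate == ival_pred] <- "150"
  r4 <- validate_statement(reshape(m4), bundle)
  expect_true(any(r4$violations$rule == "maxInclusive"))
})

test_that("maxCount and full-dialect mutants are detected", {
  set.seed(83)
  subj <- position_spec("SUBJ", constraint_spec("resource",
                                                value_class = wd("Q35120")))
  sch <- define_statement_type("tags",
    subject_spec = subj,
    object_specs = list(position_spec("TAG",
      constraint_spec("literal", datatype = "text"), max_values = 1)))
  st <- create_statement(sch, resource_ref("https://example.org/e/1", "e"),
                         list(TAG = typed_literal("a")))
  g <- to_light_graph(st, sch)
  vocab <- rosetta_vocabulary()
  extra <- g_add(g, lit_triple(st$statement_iri,
                               position_property(vocab, TRUE, TRUE, 1), "b"))
  r <- validate_statement(extra, generate_shape(sch, "light"))
  expect_true(any(r$violations$rule == "maxCount"))
  # full dialect: remove a required position instance
  a <- create_anchor(st, sch)
  fg <- as.data.frame(to_full_graph(a))
  fg2 <- fg[!grepl("/pos/tag/", fg$subject) &
              !grepl("/pos/tag/", fg$object), , drop = FALSE]
  fg2 <- structure(fg2, prefixes = default_prefixes(),
                   class = c("rosetta_graph", "data.frame"))
  rf <- validate_statement(fg2, generate_shape(sch, "full"))
  expect_true(any(rf$violations$rule == "qualifiedMinCount"))
  # full dialect: position instance without a value
  fg3 <- fg[!(grepl("/pos/tag/", fg$subject) &
                fg$predicate == rosetta_vocabulary()$value), , drop = FALSE]
  fg3 <- structure(fg3, prefixes = default_prefixes(),
                   class = c("rosetta_graph", "data.frame"))
  rf3 <- validate_statement(fg3, generate_shape(sch, "full"))
  expect_false(rf3$conforms)
})

test_that("subclass instances are admitted when the hierarchy is asserted", {
  sch <- fx_schemas()$weight
  sts <- fx_statements()
  g <- to_light_graph(sts$weight_basic, sch)
  bundle <- generate_shape(sch, "light")
  # without the ontology, the apple is not known to be a material entity
  expect_false(validate_statement(g, bundle)$conforms)
  expect_true(validate_statement(g_union(g, fixture_ontology()),
                                 bundle)$conforms)
})

test_that("closed shapes flag foreign predicates, open shapes do not", {
  sch <- fx_schemas()$weight
  sts <- fx_statements()
  g <- g_add(g_union(to_light_graph(sts$weight_basic, sch),
                     fixture_ontology()),
             lit_triple(sts$weight_basic$statement_iri,
                        "https://example.org/other/remark", "hello"))
  expect_true(validate_statement(g, generate_shape(sch, "light"))$conforms)
  closed <- validate_statement(g, generate_shape(sch, "light", closed = TRUE))
  expect_false(closed$conforms)
  expect_true(any(closed$violations$rule == "closed"))
})

test_that("validation reports serialize to JSON and Turtle", {
  sch <- fx_schemas()$weight
  rep <- validate_statement(rdf_graph(), generate_shape(sch, "light"))
  expect_true(rep$conforms)  # no focus nodes, nothing to violate
  sts <- fx_statements()
  g <- to_light_graph(sts$weight_basic, sch)
  bad <- validate_statement(g, generate_shape(sch, "light"))
  j <- jsonlite::fromJSON(report_serialize(bad, "json"))
  expect_false(j$conforms)
  ttl <- report_serialize(bad, "turtle")
  expect_true(grepl("ValidationReport", ttl))
  expect_true(g_equal(parse_turtle(ttl), parse_turtle(ttl)))
})
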