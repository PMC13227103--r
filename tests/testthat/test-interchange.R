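test_that("a nanopublication has exactly four named graphs with a clean assertion", {
  set.seed(91)
  sch <- fx_schemas(); sts <- fx_statements()
  a <- create_anchor(sts$measurement_fig1, sch$measurement)
  np <- export_nanopub(a)
  gnames <- nanopub_graphs(np)
  expect_length(gnames, 4L)
  expect_setequal(sub("^.*#", "", gnames),
                  c("head", "assertion", "provenance", "pubinfo"))
  df <- as.data.frame(np$graph)
  head_g <- df[df$graph == paste0(np$np_iri, "#head"), ]
  expect_setequal(
    head_g$object[head_g$predicate != RDF_TYPE],
    setdiff(gnames, paste0(np$np_iri, "#head")))
  # the assertion graph carries no metadata triple
  vocab <- rosetta_vocabulary()
  meta_preds <- c(vocab$version_number, vocab$creator, vocab$created_at,
                  vocab$author, vocab$certainty, vocab$extraction_method,
                  vocab$imported_from, vocab$modifiable, vocab$deleted_at)
  assertion <- df[df$graph == paste0(np$np_iri, "#assertion"), ]
  expect_false(any(assertion$predicate %in% meta_preds))
  # assertion equals the version graph minus its metadata triples
  vg <- as.data.frame(to_full_graph(a))
  vg <- vg[!is.na(vg$graph), ]
  vg_content <- vg[!vg$predicate %in% meta_preds, c("subject", "predicate",
                                                    "object")]
  expect_setequal(paste(assertion$subject, assertion$predicate,
                        assertion$object),
                  paste(vg_content$subject, vg_content$predicate,
                        vg_content$object))
  # metadata went to the other graphs instead
  prov <- df[df$graph == paste0(np$np_iri, "#provenance"), ]
  expect_true(vocab$certainty %in% prov$predicate)
  pubinfo <- df[df$graph == paste0(np$np_iri, "#pubinfo"), ]
  expect_true(all(c(vocab$creator, vocab$created_at) %in% pubinfo$predicate))
})

test_that("each version yields its own nanopublication; deleted versions refuse", {
  set.seed(92)
  sch <- fx_schemas()$weight
  sts <- fx_statements()
  a <- update_statement(create_anchor(sts$weight_basic, sch),
                        list(VALUE = typed_literal("242.00", "float")),
                        editor = "e2")
  np1 <- export_nanopub(a, version_number = 1)
  np2 <- export_nanopub(a, version_number = 2)
  expect_false(identical(np1$np_iri, np2$np_iri))
  expect_true(grepl("Nanopublication", write_trig(np1$graph)))
  a_del <- soft_delete(a, "mod", version_number = 2)
  expect_error(export_nanopub(a_del, version_number = 2), "deleted")
  # the TriG output parses back to the same quads
  expect_true(g_equal(np1$graph, parse_turtle(write_trig(np1$graph))))
})

test_that("the OBI- and OBOE-style cross-walks reproduce the five/six-triple chains", {
  set.seed(93)
  sch <- fx_schemas()$weight
  sts <- fx_statements()
  obi <- apply_crosswalk(sts$weight_basic, crosswalk_obi(sch), sch)
  oboe <- apply_crosswalk(sts$weight_basic, crosswalk_oboe(sch), sch)
  counts <- c(count_crosswalk_triples(obi), count_crosswalk_triples(oboe))
  expect_identical(max(counts), 6L)
  expect_identical(min(counts), 5L)
  # unit passed through the entity map into the target vocabulary
  expect_true("http://purl.obolibrary.org/obo/UO_0000021" %in% obi$object)
  expect_false(wd("Q41803") %in% obi$object)
  # every bound value appears in the target
  for (lex in c("241.68"))
    expect_true(lex %in% obi$object && lex %in% oboe$object)
  expect_true("https://example.org/sample/apple-1" %in% obi$object)
  # output lives in a named graph identified by the statement IRI
  expect_identical(unique(stats::na.omit(obi$graph)),
                   sts$weight_basic$statement_iri)
})

test_that("the tabular cross-walk emits the statement IRI in its own column", {
  sts <- fx_statements()
  sch <- fx_schemas()$weight
  row <- apply_crosswalk(sts$weight_basic, crosswalk_tabular(sch), sch)
  expect_identical(names(row),
                   c("statement_iri", "subject", "quality", "value", "unit"))
  expect_identical(row$statement_iri, sts$weight_basic$statement_iri)
  expect_identical(row$value, "241.68")
  expect_identical(row$unit, wd("Q41803"))
  f <- tempfile(fileext = ".csv")
  write_crosswalk_csv(row, f)
  expect_identical(utils::read.csv(f, check.names = FALSE)$value, 241.68)
})

test_that("cross-walks are invertible when the entity map is a bijection", {
  sts <- fx_statements()
  sch <- fx_schemas()$weight
  spec <- crosswalk_obi(sch)
  inv <- invert_crosswalk(apply_crosswalk(sts$weight_basic, spec, sch),
                          spec, sch)
  expect_identical(inv$subject, "https://example.org/sample/apple-1")
  expect_identical(inv$bindings$VALUE, "241.68")
  expect_identical(inv$bindings$UNIT, wd("Q41803"))
})

test_that("cross-walk errors name unmapped roles and missing entity mappings", {
  sts <- fx_statements()
  sch <- fx_schemas()$weight
  incomplete <- crosswalk_spec(sch$type_iri, "custom",
    nodes = c(datum = "https://example.org/class/datum"),
    edges = list(list(from = "datum", pred = "https://example.org/p/about",
                      to = "subject")))
  expect_error(apply_crosswalk(sts$weight_basic, incomplete, sch),
               "required role: VALUE|VALUE")
  unmapped <- crosswalk_obi(sch, unit_map = c())
  expect_error(apply_crosswalk(sts$weight_basic, unmapped, sch),
               "no entity mapping.*Q41803")
  expect_error(apply_crosswalk(sts$meet_sarah, crosswalk_obi(sch), sch),
               "does not match")
})

test_that("generated SPARQL is well-formed and matches an external engine", {
  set.seed(94)
  corpus <- make_fixtures(94, n_per_type = 6)
  store <- corpus_store(corpus)
  q <- slot_query(corpus$schemas$weight,
                  list(VALUE = filter_range(150, 400)))
  sparql <- build_query(q)
  expect_true(grepl("SELECT DISTINCT", sparql))
  hits <- run_slot_query(store, q)
  trig <- tempfile(fileext = ".trig"); rq <- tempfile(fileext = ".rq")
  writeLines(write_trig(store_graph(store)), trig, sep = "")
  writeLines(sparql, rq)
  out <- run_python(sprintf(paste0(
    "import rdflib\n",
    "d = rdflib.Dataset(default_union=True)\n",
    "d.parse('%s', format='trig')\n",
    "res = sorted(set(str(r[0]) for r in d.query(open('%s').read())))\n",
    "print('N', len(res))\n",
    "print('\\n'.join(res))\n"), trig, rq))
  expect_true(any(grepl(paste("N", length(hits)), out)))
  expect_true(all(hits %in% out))
})

test_that("slot-query results equal a brute-force filter over the records", {
  set.seed(95)
  corpus <- make_fixtures(95, n_per_type = 10)
  store <- corpus_store(corpus)
  sch <- corpus$schemas
  brute <- function(type, pred) {
    hits <- character(0)
    for (a in store$anchors) {
      if (a$type_iri != sch[[type]]$type_iri) next
      if (pred(resolve_current(a)$statement)) hits <- c(hits, a$anchor_iri)
    }
    sort(unname(hits))
  }
  # subject class filter
  q1 <- slot_query(sch$weight, list(subject = filter_class(wd("Q89"))))
  expect_identical(run_slot_query(store, q1),
                   brute("weight", function(st)
                     any(vapply(st$subject_bindings, function(b)
                       identical(b$class_iri, wd("Q89")), logical(1)))))
  # numeric range filter
  q2 <- slot_query(sch$weight, list(VALUE = filter_range(200, 300)))
  expect_identical(run_slot_query(store, q2),
                   brute("weight", function(st) {
                     v <- as.numeric(st$bindings$VALUE[[1]]$lexical)
                     v >= 200 && v <= 300
                   }))
  # exact resource filter
  q3 <- slot_query(sch$travel,
                   list(DESTINATION_LOCATION = filter_resource(wd("Q90"))))
  expect_identical(run_slot_query(store, q3),
                   brute("travel", function(st)
                     any(vapply(st$bindings$DESTINATION_LOCATION %||% list(),
                                function(b) identical(b$iri, wd("Q90")),
                                logical(1)))))
  # no filters: all statements of the type
  q4 <- slot_query(sch$meet)
  expect_identical(run_slot_query(store, q4),
                   brute("meet", function(st) TRUE))
  # current-version semantics: updates and deletions are respected
  a <- store$anchors[[run_slot_query(store, q2)[1]]]
  a2 <- update_statement(a, list(VALUE = typed_literal("999.00", "float")),
                         editor = "e")
  store2 <- store_add(store, a2)
  expect_false(a$anchor_iri %in% run_slot_query(store2, q2))
  store3 <- store_add(store, soft_delete(a, "mod"))
  expect_false(a$anchor_iri %in% run_slot_query(store3, q2))
  expect_error(slot_query(sch$weight, list(NOPE = filter_literal("x"))),
               "unknown role")
})

test_that("facet counts equal a brute-force tally", {
  set.seed(96)
  corpus <- make_fixtures(96, n_per_type = 8)
  store <- corpus_store(corpus)
  sch <- corpus$schemas
  fc <- facet_counts(store, sch$weight$type_iri)
  tally <- list()
  for (a in store$anchors) {
    if (a$type_iri != sch$weight$type_iri) next
    st <- resolve_current(a)$statement
    for (b in st$subject_bindings) {
      k <- b$label
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  expect_identical(as.list(fc$subject[sort(names(fc$subject))]),
                   tally[sort(names(tally))])
  expect_identical(sum(fc$UNIT), sum(fc$subject))
  # empty store gives an empty map
  expect_length(facet_counts(rosetta_store(fx_registry()),
                             sch$weight$type_iri), 0L)
  # multi-valued positions count each value once per statement
  fct <- facet_counts(store, sch$travel$type_iri)
  n_via_vals <- 0L
  for (a in store$anchors) {
    if (a$type_iri != sch$travel$type_iri) next
    n_via_vals <- n_via_vals +
      length(resolve_current(a)$statement$bindings$VIA %||% list())
  }
  expect_identical(sum(fct$VIA %||% integer(0)), n_via_vals)
})
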