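test_that("derived templates follow schema order, subject first", {
  sch <- fx_schemas()
  expect_identical(
    template_to_string(derive_label_template(sch$travel), sch$travel),
    "PERSON travels by TRANSPORTATION from DEPARTURE_LOCATION to DESTINATION_LOCATION via VIA on the DATETIME")
  expect_identical(
    template_to_string(derive_label_template(sch$measurement), sch$measurement),
    "This MATERIAL ENTITY has a QUALITY of MAIN_VALUE UNIT (INTERVAL_VALUE% conf. interval: LOWER_VALUE–UPPER_VALUE UNIT)")
  # zero-object schema renders as SUBJECT VERB
  sleeps <- define_statement_type("sleeps",
    subject_spec = position_spec("PERSON",
      constraint_spec("resource", value_class = wd("Q215627"))))
  expect_identical(template_to_string(derive_label_template(sleeps), sleeps),
                   "PERSON sleeps")
})

test_that("the measurement worked example renders with value and en-dash range", {
  sch <- fx_schemas(); sts <- fx_statements()
  tpl <- derive_label_template(sch$measurement)
  out <- render_label(tpl, sts$measurement_fig1, sch$measurement)
  expect_identical(out,
    "This apple has a weight of 241.68 grams (95% conf. interval: 241.31–242.05 grams)")
  expect_identical(render_label(tpl, sts$measurement_intro, sch$measurement),
    "This apple has a weight of 212.45 grams (95% conf. interval: 212.44–212.47 grams)")
})

test_that("empty optional positions drop their pre/post texts and groups", {
  sch <- fx_schemas(); sts <- fx_statements()
  tpl <- derive_label_template(sch$measurement)
  out <- render_label(tpl, sts$measurement_orange, sch$measurement)
  expect_identical(out, "This orange has a weight of 114.21 grams")
  expect_false(grepl("conf|\\(|\\)", out))
  # travel without VIA: no "via" text
  tt <- derive_label_template(sch$travel)
  anna <- render_label(tt, sts$travel_anna, sch$travel)
  expect_identical(anna,
    "Anna travels by train from Berlin to Paris on the 21st of April 2023")
  expect_false(grepl("via", anna))
})

test_that("multi-valued positions join with a serial comma in order", {
  sch <- fx_schemas(); sts <- fx_statements()
  tt <- derive_label_template(sch$travel)
  out <- render_label(tt, sts$travel_via, sch$travel)
  expect_true(grepl(
    "via Osnabrück, Hengelo, Utrecht, and Rotterdam on the", out))
  # two values use a bare "and"
  two <- create_statement(sch$meet,
    list(resource_ref("https://example.org/p/sarah", "Sarah",
                      class_iri = wd("Q215627")),
         resource_ref("https://example.org/p/anna", "Anna",
                      class_iri = wd("Q215627"))),
    list(PERSON = list(resource_ref("https://example.org/p/bob", "Bob",
                                    class_iri = wd("Q215627")),
                       resource_ref("https://example.org/p/chris", "Christopher",
                                    class_iri = wd("Q215627"))),
         DATE = typed_literal("2021-07-04", "date",
                              display = "4th of July 2021")))
  out2 <- render_label(derive_label_template(sch$meet), two, sch$meet)
  expect_identical(out2,
    "Sarah and Anna met Bob and Christopher on 4th of July 2021")
})

test_that("rendering is lossless for lexical forms and errors on empty required slots", {
  set.seed(71)
  sch <- fx_schemas()$measurement
  sts <- fx_statements()
  out <- render_label(derive_label_template(sch), sts$measurement_fig1, sch)
  for (lex in c("241.68", "241.31", "242.05", "95"))
    expect_identical(lengths(regmatches(out, gregexpr(lex, out, fixed = TRUE))),
                     1L, label = lex)
  broken <- sts$measurement_fig1
  broken$bindings$MAIN_VALUE <- NULL
  expect_error(render_label(derive_label_template(sch), broken, sch),
               "MAIN_VALUE")
})

test_that("pre/postpositions appear iff their slot is non-empty (property)", {
  set.seed(72)
  marker_pre <- "PREMARK"; marker_post <- "POSTMARK"
  subj <- position_spec("SUBJ", constraint_spec("resource",
                                                value_class = wd("Q35120")))
  sch <- define_statement_type("relates to",
    subject_spec = subj,
    object_specs = list(
      position_spec("A", constraint_spec("literal", datatype = "text"),
                    pre = marker_pre, required = FALSE),
      position_spec("B", constraint_spec("literal", datatype = "text"),
                    post = marker_post, required = FALSE)))
  tpl <- derive_label_template(sch)
  for (i in 1:10) {
    with_a <- runif(1) < 0.5; with_b <- runif(1) < 0.5
    st <- create_statement(sch, resource_ref("https://example.org/e/s", "s"),
      c(if (with_a) list(A = typed_literal("aval")),
        if (with_b) list(B = typed_literal("bval"))))
    out <- render_label(tpl, st, sch)
    expect_identical(grepl(marker_pre, out), with_a)
    expect_identical(grepl(marker_post, out), with_b)
  }
})

test_that("negated statements are rendered as explicit negations", {
  sch <- fx_schemas()$weight
  st <- create_statement(sch,
    resource_ref("https://example.org/s/a1", "apple"),
    list(VALUE = typed_literal("241.68", "float"),
         UNIT = resource_ref(wd("Q41803"), "grams")),
    negated = TRUE)
  out <- render_label(derive_label_template(sch), st, sch)
  expect_identical(out,
    "It is not the case that This apple has a weight of 241.68 grams")
})

test_that("rendering accepts versions and is deterministic", {
  set.seed(73)
  sch <- fx_schemas(); sts <- fx_statements()
  a <- create_anchor(sts$weight_basic, sch$weight)
  tpl <- derive_label_template(sch$weight)
  expect_identical(render_label(tpl, resolve_current(a), sch$weight),
                   render_label(tpl, sts$weight_basic, sch$weight))
})

test_that("mind-maps have one predicate node per statement and merge shared resources", {
  sch <- fx_schemas(); sts <- fx_statements(); reg <- fx_registry()
  mm <- render_mindmap(list(sts$travel_anna), reg)
  expect_identical(sum(mm$nodes$kind == "predicate"), 1L)
  expect_identical(nrow(mm$nodes), 6L)  # predicate + subject + 4 bound values
  expect_identical(nrow(mm$edges), 5L)
  # shared subject Anna appears once across two statements
  mm2 <- render_mindmap(list(sts$travel_anna, sts$travel_via), reg)
  expect_identical(sum(mm2$nodes$label == "Anna"), 1L)
  expect_identical(sum(mm2$nodes$kind == "predicate"), 2L)
  # empty input gives an empty pattern
  mm0 <- render_mindmap(list(), reg)
  expect_identical(nrow(mm0$nodes), 0L)
  expect_identical(nrow(mm0$edges), 0L)
})

test_that("mind-map exports are well-formed DOT and JSON", {
  sch <- fx_schemas(); sts <- fx_statements(); reg <- fx_registry()
  mm <- render_mindmap(list(sts$meet_sarah), reg)
  dot <- mindmap_to_dot(mm)
  expect_true(startsWith(dot, "digraph"))
  expect_true(grepl("label=\"PERSON\"", dot))
  parsed <- jsonlite::fromJSON(mindmap_to_json(mm))
  expect_setequal(names(parsed), c("nodes", "edges"))
  expect_identical(nrow(parsed$edges), nrow(mm$edges))
})
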