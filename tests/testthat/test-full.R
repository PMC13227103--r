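mk_weight_anchor <- function(value = "241.0") {
  sch <- fx_schemas()$weight
  st <- create_statement(sch,
    resource_ref("https://example.org/s/a1", "apple", class_iri = wd("Q89")),
    list(VALUE = typed_literal(value, "float"),
         UNIT = resource_ref(wd("Q41803"), "grams")),
    metadata = provenance_metadata(creator = "curator-1",
                                   created_at = "2024-03-01T09:00:00Z"))
  create_anchor(st, sch)
}

upd_value <- function(anchor, value, editor = "curator-2",
                      created_at = "2024-03-02T09:00:00Z")
  update_statement(anchor, list(VALUE = typed_literal(value, "float")),
                   editor = editor, created_at = created_at)

test_that("anchors start at version 1 and link content only through position instances", {
  set.seed(51)
  a <- mk_weight_anchor()
  expect_identical(resolve_current(a)$version_number, 1L)
  g <- to_full_graph(a)
  df <- as.data.frame(g)
  vocab <- rosetta_vocabulary()
  v1 <- a$versions[[1]]$version_iri
  # the subject resource is never directly linked to the statement instance
  expect_false(any(df$subject %in% c(a$anchor_iri, v1) &
                     df$object == "https://example.org/s/a1" &
                     df$predicate != vocab$value &
                     !grepl("/pos/", df$subject)))
  subj_inst <- df$object[df$subject == v1 & df$predicate == vocab$subject]
  expect_length(subj_inst, 1)
  expect_true(vocab$subject_position_class %in%
                df$object[df$subject == subj_inst & df$predicate == RDF_TYPE])
  expect_identical(
    df$object[df$subject == subj_inst & df$predicate == vocab$value],
    "https://example.org/s/a1")
  # anchor carries schema + version links, and no bindings of its own
  expect_true(any(df$subject == a$anchor_iri &
                    df$predicate == vocab$has_data_schema))
  expect_false(any(df$subject == a$anchor_iri &
                     df$predicate %in% c(vocab$subject,
                                         vocab$required_object_position)))
})

test_that("context links are emitted with their derivable inverse", {
  set.seed(52)
  sch <- fx_schemas()$meet
  st <- fx_statements()$meet_sarah
  a <- create_anchor(st, sch, context_iri = "https://example.org/pub/42")
  df <- as.data.frame(to_full_graph(a))
  vocab <- rosetta_vocabulary()
  expect_identical(df$object[df$predicate == vocab$has_context],
                   "https://example.org/pub/42")
  expect_identical(df$subject[df$predicate == vocab$has_statement],
                   "https://example.org/pub/42")
})

test_that("updates append versions and never touch earlier ones", {
  set.seed(53)
  a <- mk_weight_anchor("241.0")
  g1 <- to_full_graph(a)
  a2 <- upd_value(a, "241.68")
  expect_identical(vapply(a2$versions, `[[`, integer(1), "version_number"),
                   1:2)
  expect_identical(resolve_current(a2)$version_number, 2L)
  expect_identical(
    resolve_current(a2)$statement$bindings$VALUE[[1]]$lexical, "241.68")
  # append-only at the triple level
  expect_true(g_contains(to_full_graph(a2), g1))
  a4 <- upd_value(upd_value(a2, "242.0"), "243.0")
  expect_identical(vapply(a4$versions, `[[`, integer(1), "version_number"),
                   1:4)
  # an invalid update leaves the version list unchanged
  expect_error(update_statement(a4, list(VALUE = typed_literal("nope", "text")),
                                editor = "x"),
               "datatype")
  expect_length(a4$versions, 4)
})

test_that("resolve_current returns the highest non-deleted version", {
  set.seed(54)
  a <- upd_value(upd_value(mk_weight_anchor("1.0"), "2.0"), "3.0")
  expect_identical(resolve_current(a)$version_number, 3L)
  a_del <- soft_delete(a, who = "mod", version_number = 3)
  expect_identical(resolve_current(a_del)$version_number, 2L)
  # filter-then-max oracle over random deletion patterns
  for (i in 1:10) {
    nums <- 1:5
    dead <- sample(nums, sample.int(4, 1))
    b <- mk_weight_anchor("1.0")
    for (k in 2:5) b <- upd_value(b, paste0(k, ".0"))
    for (d in dead) b <- soft_delete(b, "mod", version_number = d)
    expect_identical(resolve_current(b)$version_number,
                     max(setdiff(nums, dead)))
  }
})

test_that("soft delete keeps metadata accessible and blocks edits", {
  set.seed(55)
  a <- mk_weight_anchor()
  expect_s3_class(anchor_content(a), "rosetta_statement")
  a_del <- soft_delete(a, who = "moderator", when = "2024-04-01T00:00:00Z")
  md <- anchor_metadata(a_del)
  expect_true(md$deleted)
  expect_identical(md$deleted_by, "moderator")
  expect_identical(md$creator, "curator-1")
  content <- anchor_content(a_del)
  expect_true(content$deleted)
  expect_error(update_statement(a_del, list(), editor = "x"), "deleted")
  expect_error(soft_delete(a_del, who = "again"), "already deleted")
  # deletion only adds triples, and the deleted-at triple is serialized
  g_before <- to_full_graph(a); g_after <- to_full_graph(a_del)
  expect_true(g_contains(g_after, g_before))
  vocab <- rosetta_vocabulary()
  expect_identical(
    g_match(g_after, s = a$anchor_iri, p = vocab$deleted_at)$object,
    "2024-04-01T00:00:00Z")
  # all versions deleted is a distinct error from a deleted anchor
  a_v <- soft_delete(mk_weight_anchor(), who = "m", version_number = 1)
  expect_error(resolve_current(a_v), "all versions")
  expect_error(update_statement(soft_delete(mk_weight_anchor(), "m"),
                                list(), editor = "x"),
               "deleted anchor")
})

test_that("non-modifiable anchors refuse updates", {
  set.seed(56)
  sch <- fx_schemas()$weight
  st <- create_statement(sch,
    resource_ref("https://example.org/s/a1", "apple"),
    list(VALUE = typed_literal("1.0", "float"),
         UNIT = resource_ref(wd("Q41803"), "grams")),
    metadata = provenance_metadata(creator = "c", modifiable = FALSE))
  a <- create_anchor(st, sch)
  expect_error(update_statement(a, list(), editor = "x"), "not modifiable")
})

test_that("position history flags changes exactly where a naive diff does", {
  set.seed(57)
  a <- upd_value(mk_weight_anchor("241.0"), "241.68")
  h <- position_history(a, "VALUE")
  expect_identical(h$version_number, 1:2)
  expect_identical(h$changed, c(FALSE, TRUE))
  h_unit <- position_history(upd_value(a, "243.0"), "UNIT")
  expect_identical(nrow(h_unit), 3L)
  expect_false(any(h_unit$changed))
  expect_error(position_history(a, "NOPE"), "unknown role")
  # randomized edit sequences against a brute-force pairwise comparison
  for (i in 1:10) {
    vals <- as.character(sample(c("1.0", "2.0", "3.0"), 6, replace = TRUE))
    b <- mk_weight_anchor(vals[1])
    for (v in vals[-1]) b <- upd_value(b, v)
    h <- position_history(b, "VALUE")
    oracle <- c(FALSE, vals[-1] != vals[-length(vals)])
    expect_identical(h$changed, oracle, label = paste(vals, collapse = ","))
  }
})

test_that("contributor metadata aggregates over versions", {
  set.seed(58)
  a <- upd_value(mk_weight_anchor(), "242.0", editor = "curator-2",
                 created_at = "2024-03-05T10:00:00Z")
  ctr <- contributors(a)
  expect_identical(ctr$contributors, c("curator-1", "curator-2"))
  expect_identical(ctr$last_update, "2024-03-05T10:00:00Z")
  one <- contributors(mk_weight_anchor())
  expect_identical(one$contributors, "curator-1")
  dup <- upd_value(mk_weight_anchor(), "242.0", editor = "curator-1")
  expect_identical(contributors(dup)$contributors, "curator-1")
})

test_that("logical property annotations attach to position instances", {
  set.seed(59)
  subj <- position_spec("WHOLE", constraint_spec("resource",
                                                 value_class = wd("Q35120")))
  sch <- define_statement_type("has part",
    subject_spec = subj,
    object_specs = list(position_spec("PART",
      constraint_spec("resource", value_class = wd("Q35120")))))
  st <- create_statement(sch, resource_ref("https://example.org/e/hand", "hand"),
    list(PART = resource_ref("https://example.org/e/thumb", "thumb")))
  a <- create_anchor(st, sch)
  a <- annotate_logical_property(a, 1, "PART", "transitive", TRUE)
  df <- as.data.frame(to_full_graph(a))
  vocab <- rosetta_vocabulary()
  ann <- df[df$predicate == paste0(vocab$ns, "transitive"), , drop = FALSE]
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$object, "true")
  expect_true(grepl("/pos/part/", ann$subject))
  a_false <- annotate_logical_property(a, 1, "PART", "transitive", FALSE)
  df2 <- as.data.frame(to_full_graph(a_false))
  expect_identical(df2$object[df2$predicate == paste0(vocab$ns, "transitive")],
                   "false")
  expect_error(annotate_logical_property(a, 1, "NOPE", "transitive", TRUE),
               "unknown role")
  # annotations survive the graph round-trip
  back <- from_full_graph(to_full_graph(a), schema_registry(list(sch)))
  expect_true(isTRUE(back$versions[[1]]$annotations$PART$transitive))
})

test_that("full graphs round-trip losslessly, preserving multi-value order", {
  set.seed(60)
  reg <- fx_registry(); sch <- fx_schemas(); sts <- fx_statements()
  a <- create_anchor(sts$travel_via, sch$travel)
  back <- from_full_graph(to_full_graph(a), reg)
  expect_true(anchors_equal(a, back))
  expect_identical(
    vapply(resolve_current(back)$statement$bindings$VIA, `[[`,
           character(1), "label"),
    c("Osnabrück", "Hengelo", "Utrecht", "Rotterdam"))
  # all packaged fixtures
  corpus <- make_fixtures(60, n_per_type = 0)
  for (e in corpus$statements) {
    an <- create_anchor(e$statement, corpus$schemas[[e$type]])
    expect_true(anchors_equal(an, from_full_graph(to_full_graph(an), reg)),
                label = e$name)
  }
  # randomized multi-version anchors
  for (i in 1:10) {
    b <- mk_weight_anchor("1.0")
    for (k in seq_len(sample.int(3, 1)))
      b <- upd_value(b, format(round(runif(1, 1, 99), 2), nsmall = 2))
    if (runif(1) < 0.3) b <- soft_delete(b, "m", version_number = 1)
    expect_true(anchors_equal(b, from_full_graph(to_full_graph(b), reg)),
                label = paste("random anchor", i))
  }
  # dangling position instance is a parse error
  g <- to_full_graph(a)
  vocab <- rosetta_vocabulary()
  g2 <- as.data.frame(g)
  g2 <- g2[!(g2$predicate == vocab$value &
               grepl("/pos/via/2", g2$subject)), , drop = FALSE]
  g2 <- structure(g2, prefixes = attr(g, "prefixes"),
                  class = c("rosetta_graph", "data.frame"))
  expect_error(from_full_graph(g2, reg), "dangling")
})

test_that("the simplified single-link variant serializes and parses", {
  set.seed(61)
  sts <- fx_statements(); sch <- fx_schemas()
  a <- create_anchor(sts$meet_sarah, sch$meet)
  g <- to_full_graph(a, simplified = TRUE)
  vocab <- rosetta_vocabulary()
  expect_false(vocab$required_object_position %in% g$predicate)
  expect_true(vocab$has_object_position %in% g$predicate)
  expect_true(anchors_equal(a, from_full_graph(g, fx_registry())))
})

test_that("TriG export puts each version in its own named graph", {
  set.seed(62)
  a <- upd_value(mk_weight_anchor(), "242.0")
  g <- to_full_graph(a)
  gnames <- unique(stats::na.omit(g$graph))
  expect_setequal(gnames, vapply(a$versions, `[[`, character(1), "version_iri"))
  txt <- write_trig(g)
  expect_true(all(vapply(gnames, function(x) grepl(x, txt, fixed = TRUE),
                         logical(1))))
  expect_true(g_equal(g, parse_turtle(txt)))
})
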