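#' Nanopublications, schema cross-walks, and slot queries
#'
#' A statement version can be published as a nanopublication (four named
#' graphs: head, assertion, provenance, publication info); translated into
#' other measurement schemata via declarative cross-walks (OBI-style,
#' OBOE-style, a table row, or custom node/edge templates); and queried via
#' generated SPARQL or the in-package slot-query evaluator.
#' @name interchange
NULL

.np_metadata_preds <- function(vocab)
  c(vocab$version_number, vocab$version_identifier, vocab$creator,
    vocab$created_at, vocab$author, vocab$certainty,
    vocab$extraction_method, vocab$imported_from, vocab$modifiable,
    vocab$deleted_at, vocab$deleted_by)

#' Export a statement version as a nanopublication
#'
#' The assertion graph is the version's statement subgraph with every
#' metadata triple stripped. Metadata about the assertion itself
#' (certainty, extraction method, author of the claim) goes to the
#' provenance graph; metadata about the nanopublication (creator,
#' creation date, version number) goes to the publication-info graph.
#'
#' @param anchor a `rosetta_anchor`
#' @param version_number which version to export; default: the current one
#' @return a `rosetta_nanopub` (fields `np_iri`, `graph`)
#' @export
export_nanopub <- function(anchor, version_number = NULL) {
  vocab <- rosetta_vocabulary(anchor$schema$base)
  v <- if (is.null(version_number)) resolve_current(anchor) else {
    idx <- which(vapply(anchor$versions, `[[`, integer(1),
                        "version_number") == version_number)
    if (!length(idx)) stop("no version numbered ", version_number)
    anchor$versions[[idx]]
  }
  if (!is.null(v$deleted_at))
    stop("version ", v$version_number,
         " is soft-deleted and cannot be published", call. = FALSE)
  np <- mint_iri("nanopub", anchor$schema$base)
  NP <- function(x) paste0("http://www.nanopub.org/nschema#", x)
  gh <- paste0(np, "#head"); ga <- paste0(np, "#assertion")
  gp <- paste0(np, "#provenance"); gi <- paste0(np, "#pubinfo")
  g <- rdf_graph(prefixes = c(default_prefixes(), rosetta = vocab$ns))
  g <- g_add(g,
             triple(np, RDF_TYPE, NP("Nanopublication"), graph = gh),
             triple(np, NP("hasAssertion"), ga, graph = gh),
             triple(np, NP("hasProvenance"), gp, graph = gh),
             triple(np, NP("hasPublicationInfo"), gi, graph = gh))
  content <- .version_graph_rows(anchor, v, vocab, simplified = FALSE,
                                 gname = ga)
  content <- content[!content$predicate %in% .np_metadata_preds(vocab), ,
                     drop = FALSE]
  g <- g_add(g, content)
  if (!is.null(v$certainty))
    g <- g_add(g, lit_triple(ga, vocab$certainty,
                             format(v$certainty, scientific = FALSE),
                             xsd_iri("decimal"), graph = gp))
  if (!is.null(anchor$metadata$extraction_method))
    g <- g_add(g, lit_triple(ga, vocab$extraction_method,
                             anchor$metadata$extraction_method, graph = gp))
  if (!is.null(v$author))
    g <- g_add(g, lit_triple(ga, vocab$author, v$author, graph = gp))
  if (!is.null(anchor$metadata$imported_from))
    g <- g_add(g, lit_triple(ga, vocab$imported_from,
                             anchor$metadata$imported_from, graph = gp))
  if (!is.null(anchor$context_iri))
    g <- g_add(g, triple(ga, vocab$has_context, anchor$context_iri,
                         graph = gp))
  g <- g_add(g,
             lit_triple(np, vocab$creator, v$creator %||% "unknown", graph = gi),
             lit_triple(np, vocab$created_at, v$created_at,
                        xsd_iri("dateTime"), graph = gi),
             lit_triple(np, vocab$version_number,
                        as.character(v$version_number), xsd_iri("integer"),
                        graph = gi))
  if (!is.null(v$identifier))
    g <- g_add(g, lit_triple(np, vocab$version_identifier, v$identifier,
                             graph = gi))
  structure(list(np_iri = np, graph = g_canonical(g)),
            class = "rosetta_nanopub")
}

#' Named graphs of a nanopublication
#' @param np a `rosetta_nanopub`
#' @return character vector of the named-graph IRIs
#' @export
nanopub_graphs <- function(np) unique(stats::na.omit(np$graph$graph))

#' @export
print.rosetta_nanopub <- function(x, ...) {
  cat("<rosetta_nanopub> ", x$np_iri, " (", length(nanopub_graphs(x)),
      " named graphs, ", nrow(x$graph), " quads)\n", sep = "")
  invisible(x)
}

## ---- cross-walks ----------------------------------------------------------

#' Declarative schema cross-walk specification
#'
#' Maps statements of one type onto a target graph pattern (or table row).
#' Graph targets are described by intermediate `nodes` (name -> class IRI;
#' one instance per statement is minted deterministically from the
#' statement IRI) and `edges` (from, predicate, to), where endpoints may be
#' `"statement"`, a node name, `"subject"`, a role label, or a constant
#' name. Resource values of roles listed in `mapped_roles` are translated
#' through `entity_map` (source IRI -> target IRI); a missing mapping is an
#' error, as the target schema's constraints could not be met otherwise.
#'
#' @param source_type_iri statement type the spec applies to
#' @param target "obi-style", "oboe-style", "tabular" or "custom"
#' @param nodes named character vector: node name -> class IRI
#' @param edges list of `list(from =, pred =, to =)`
#' @param constants named character vector: constant name -> target IRI
#' @param entity_map named character vector: source IRI -> target IRI
#' @param mapped_roles roles whose resource values must pass the entity map
#' @param columns for tabular targets: named character vector column ->
#'   "statement", "subject", a role label or a constant name
#' @return a `rosetta_crosswalk`
#' @export
crosswalk_spec <- function(source_type_iri,
                           target = c("custom", "obi-style", "oboe-style",
                                      "tabular"),
                           nodes = c(), edges = list(), constants = c(),
                           entity_map = c(), mapped_roles = character(),
                           columns = c()) {
  target <- match.arg(target)
  structure(list(source_type_iri = source_type_iri, target = target,
                 nodes = nodes, edges = edges, constants = constants,
                 entity_map = entity_map, mapped_roles = mapped_roles,
                 columns = columns),
            class = "rosetta_crosswalk")
}

#' Check a cross-walk covers the schema's required roles
#' @param spec a `rosetta_crosswalk`
#' @param schema the source schema
#' @return invisibly TRUE, or an error naming the unmapped role
#' @export
validate_crosswalk_spec <- function(spec, schema) {
  required <- vapply(Filter(function(p) p$required, schema$objects),
                     `[[`, character(1), "role")
  covered <- if (spec$target == "tabular") unname(spec$columns)
             else unlist(lapply(spec$edges, function(e) c(e$from, e$to)))
  missing <- setdiff(required, covered)
  if (length(missing))
    stop("cross-walk does not map required role: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

.xwalk_map_resource <- function(iri, role, spec) {
  if (!role %in% spec$mapped_roles) return(iri)
  out <- spec$entity_map[[iri]]
  if (is.null(out))
    stop("no entity mapping for ", iri, " (role ", role,
         "), required by the target schema's constraints")
  out
}

#' Apply a schema cross-walk to a statement
#'
#' Graph targets return a `rosetta_graph` whose quads live in a named graph
#' identified by the statement IRI (the statement stays referencable);
#' tabular targets return a one-row data frame with the statement IRI in a
#' dedicated column.
#'
#' @param statement a `rosetta_statement`
#' @param spec a `rosetta_crosswalk`
#' @param schema the source schema
#' @return a `rosetta_graph` or a one-row data frame
#' @export
apply_crosswalk <- function(statement, spec, schema) {
  if (statement$type_iri != spec$source_type_iri)
    stop("statement type ", statement$type_iri,
         " does not match cross-walk source ", spec$source_type_iri)
  validate_crosswalk_spec(spec, schema)
  roles <- schema_roles(schema)
  value_terms <- function(endpoint) {
    if (endpoint == "statement")
      return(list(list(term = statement$statement_iri, iri = TRUE)))
    if (endpoint %in% names(spec$nodes))
      return(list(list(term = paste0(statement$statement_iri, "/", endpoint),
                       iri = TRUE)))
    if (endpoint %in% names(spec$constants))
      return(list(list(term = spec$constants[[endpoint]], iri = TRUE)))
    bs <- if (endpoint == "subject") statement$subject_bindings
          else if (endpoint %in% roles) statement$bindings[[endpoint]]
          else stop("unknown cross-walk endpoint: ", endpoint)
    lapply(bs %||% list(), function(b) {
      if (inherits(b, "rosetta_resource"))
        list(term = .xwalk_map_resource(b$iri, endpoint, spec), iri = TRUE)
      else list(term = b$lexical, iri = FALSE, dt = b$datatype_iri)
    })
  }
  if (spec$target == "tabular") {
    row <- lapply(names(spec$columns), function(col) {
      vals <- value_terms(spec$columns[[col]])
      paste(vapply(vals, `[[`, character(1), "term"), collapse = "; ")
    })
    names(row) <- names(spec$columns)
    return(as.data.frame(row, stringsAsFactors = FALSE,
                         check.names = FALSE))
  }
  gname <- statement$statement_iri
  g <- rdf_graph(prefixes = c(default_prefixes(),
                              rosetta = rosetta_vocabulary(schema$base)$ns))
  for (nm in names(spec$nodes))
    g <- g_add(g, triple(paste0(statement$statement_iri, "/", nm), RDF_TYPE,
                         spec$nodes[[nm]], graph = gname))
  for (e in spec$edges) {
    froms <- value_terms(e$from)
    tos <- value_terms(e$to)
    for (f in froms) for (t in tos) {
      if (!f$iri) stop("edge source must be a resource: ", e$from)
      g <- if (t$iri) g_add(g, triple(f$term, e$pred, t$term, graph = gname))
           else g_add(g, lit_triple(f$term, e$pred, t$term, t$dt,
                                    graph = gname))
    }
  }
  g_canonical(g)
}

#' Count the slot-path triples of a cross-walk output graph
#'
#' rdf:type triples are excluded, mirroring [count_slot_triples()] for the
#' light dialect, so the outputs are directly comparable (three versus five
#' or six for the basic measurement).
#' @param graph cross-walk output graph
#' @return integer
#' @export
count_crosswalk_triples <- function(graph) {
  df <- as.data.frame(graph)
  sum(df$predicate != RDF_TYPE)
}

#' Extract the source bindings back out of a cross-walk output graph
#'
#' Possible when the entity map is injective; used to show the translation
#' loses no bound value.
#' @param graph output of [apply_crosswalk()]
#' @param spec the `rosetta_crosswalk` that produced it
#' @param schema the source schema
#' @return list with `subject` IRIs and `bindings` (role -> character
#'   values, resources unmapped back to source IRIs)
#' @export
invert_crosswalk <- function(graph, spec, schema) {
  if (spec$target == "tabular") stop("inversion is defined for graph targets")
  df <- as.data.frame(graph)
  stmt <- unique(stats::na.omit(df$graph))
  if (length(stmt) != 1L) stop("expected a single statement graph")
  inv <- stats::setNames(names(spec$entity_map), unname(spec$entity_map))
  node_iri <- function(endpoint) {
    if (endpoint == "statement") stmt
    else if (endpoint %in% names(spec$nodes)) paste0(stmt, "/", endpoint)
    else if (endpoint %in% names(spec$constants)) spec$constants[[endpoint]]
    else NA_character_
  }
  roles <- c("subject", schema_roles(schema))
  out <- list()
  for (e in spec$edges) {
    if (!e$to %in% roles) next
    from <- node_iri(e$from)
    vals <- df$object[df$subject == from & df$predicate == e$pred]
    if (e$to %in% spec$mapped_roles)
      vals <- vapply(vals, function(v) inv[[v]] %||% v, character(1))
    out[[e$to]] <- unname(vals)
  }
  list(subject = out[["subject"]],
       bindings = out[names(out) != "subject"])
}

## ---- built-in measurement cross-walks -------------------------------------

OBO <- function(x) paste0("http://purl.obolibrary.org/obo/", x)
OBOE <- function(x)
  paste0("http://ecoinformatics.org/oboe/oboe.1.2/oboe-core.owl#", x)

#' Built-in cross-walks for the basic measurement statement
#'
#' The OBI-style template routes the value through a scalar measurement
#' datum and a scalar value specification (six slot-path triples); the
#' OBOE-style template routes it through an observation and a measurement
#' (five). The quality is supplied as a constant: the verb of a has-weight
#' statement already fixes it, so the source schema has no quality slot,
#' while observation-centric target schemata require the explicit node.
#'
#' @param schema the basic measurement `rosetta_schema` (roles VALUE, UNIT)
#' @param quality_iri target-vocabulary IRI of the measured quality
#' @param unit_map named character vector mapping source unit IRIs to
#'   target-vocabulary unit IRIs
#' @return a `rosetta_crosswalk`
#' @export
crosswalk_obi <- function(schema,
                          quality_iri = OBO("PATO_0000128"),
                          unit_map = c("http://www.wikidata.org/entity/Q41803" =
                                         OBO("UO_0000021"))) {
  crosswalk_spec(
    source_type_iri = schema$type_iri, target = "obi-style",
    nodes = c(datum = OBO("IAO_0000032"),   # scalar measurement datum
              vspec = OBO("OBI_0001931")),  # scalar value specification
    constants = c(quality = quality_iri),
    edges = list(
      list(from = "datum", pred = OBO("IAO_0000136"), to = "subject"),
      list(from = "quality", pred = OBO("RO_0000052"), to = "subject"),
      list(from = "datum", pred = OBO("IAO_0000221"), to = "quality"),
      list(from = "datum", pred = OBO("OBI_0001938"), to = "vspec"),
      list(from = "vspec", pred = OBO("OBI_0001937"), to = "VALUE"),
      list(from = "vspec", pred = OBO("IAO_0000039"), to = "UNIT")),
    entity_map = unit_map, mapped_roles = "UNIT")
}

#' @rdname crosswalk_obi
#' @export
crosswalk_oboe <- function(schema,
                           quality_iri = "http://purl.obolibrary.org/obo/NCIT_C25208",
                           unit_map = c("http://www.wikidata.org/entity/Q41803" =
                             "http://ecoinformatics.org/oboe/oboe.1.2/oboe-standards.owl#Gram")) {
  crosswalk_spec(
    source_type_iri = schema$type_iri, target = "oboe-style",
    nodes = c(observation = OBOE("Observation"),
              measurement = OBOE("Measurement")),
    constants = c(characteristic = quality_iri),
    edges = list(
      list(from = "observation", pred = OBOE("ofEntity"), to = "subject"),
      list(from = "observation", pred = OBOE("hasMeasurement"),
           to = "measurement"),
      list(from = "measurement", pred = OBOE("ofCharacteristic"),
           to = "characteristic"),
      list(from = "measurement", pred = OBOE("hasValue"), to = "VALUE"),
      list(from = "measurement", pred = OBOE("usesStandard"), to = "UNIT")),
    entity_map = unit_map, mapped_roles = "UNIT")
}

#' @rdname crosswalk_obi
#' @export
crosswalk_tabular <- function(schema, quality_iri = "http://www.wikidata.org/entity/Q11423") {
  crosswalk_spec(
    source_type_iri = schema$type_iri, target = "tabular",
    constants = c(quality = quality_iri),
    columns = c(statement_iri = "statement", subject = "subject",
                quality = "quality", value = "VALUE", unit = "UNIT"))
}

#' Write tabular cross-walk rows as CSV
#' @param rows data frame(s) from [apply_crosswalk()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_crosswalk_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

## ---- slot queries and facets ----------------------------------------------

#' Slot-based query over a statement type
#'
#' The uniform metamodel lets a form-based UI translate per-slot input into
#' a graph query mechanically; this object captures one such form state.
#'
#' @param schema a `rosetta_schema`
#' @param filters named list: role label (or "subject") -> filter, each one
#'   of `filter_resource(iri)`, `filter_class(iri)`, `filter_literal(x)`,
#'   `filter_range(min, max)`; unnamed roles are unconstrained
#' @param dialect "full" (default; resolves only current, non-deleted
#'   versions) or "light"
#' @return a `rosetta_query`
#' @export
slot_query <- function(schema, filters = list(),
                       dialect = c("full", "light")) {
  dialect <- match.arg(dialect)
  known <- c("subject", schema_roles(schema))
  bad <- setdiff(names(filters), known)
  if (length(bad)) stop("filter on unknown role: ", paste(bad, collapse = ", "))
  structure(list(schema = schema, type_iri = schema$type_iri,
                 filters = filters, dialect = dialect),
            class = "rosetta_query")
}

#' @rdname slot_query
#' @export
filter_resource <- function(iri) list(kind = "resource", iri = iri)

#' @rdname slot_query
#' @export
filter_class <- function(iri) list(kind = "class", iri = iri)

#' @rdname slot_query
#' @export
filter_literal <- function(value) list(kind = "literal", value = as.character(value))

#' @rdname slot_query
#' @export
filter_range <- function(min = -Inf, max = Inf)
  list(kind = "range", min = min, max = max)

.sparql_term <- function(iri) paste0("<", iri, ">")

#' Generate SPARQL for a slot query
#'
#' Produces a syntactically valid SPARQL 1.1 SELECT query with one graph
#' pattern per filtered role. Full-dialect queries resolve anchors to their
#' current (highest-numbered, non-deleted) version.
#' @param query a `rosetta_query`
#' @return SPARQL text
#' @export
build_query <- function(query) {
  schema <- query$schema
  vocab <- rosetta_vocabulary(schema$base)
  lines <- character(0); i <- 0L
  slot_pattern <- function(role, var) {
    if (query$dialect == "light") {
      if (role == "subject")
        return(sprintf("  ?stmt %s %s .", .sparql_term(vocab$subject), var))
      p <- schema_position(schema, role)
      pred <- position_property(vocab, p$required,
                                p$constraint$kind == "literal", p$index)
      sprintf("  ?stmt %s %s .", .sparql_term(pred), var)
    } else {
      inst <- paste0(var, "_pos")
      if (role == "subject") {
        link <- vocab$subject; cls <- vocab$subject_position_class
      } else {
        p <- schema_position(schema, role)
        link <- if (p$required) vocab$required_object_position
                else vocab$optional_object_position
        cls <- position_class_iri(schema, role)
      }
      paste(sprintf("  ?version %s %s .", .sparql_term(link), inst),
            sprintf("  %s a %s .", inst, .sparql_term(cls)),
            sprintf("  %s %s %s .", inst, .sparql_term(vocab$value), var),
            sep = "\n")
    }
  }
  filter_clause <- function(f, var) {
    switch(f$kind,
      resource = sprintf("  FILTER(%s = %s)", var, .sparql_term(f$iri)),
      class = sprintf("  %s a %s .", var, .sparql_term(f$iri)),
      literal = sprintf("  FILTER(STR(%s) = \"%s\")", var,
                        escape_literal(f$value)),
      range = {
        parts <- c(if (is.finite(f$min)) sprintf("xsd:decimal(%s) >= %s",
                                                 var, f$min),
                   if (is.finite(f$max)) sprintf("xsd:decimal(%s) <= %s",
                                                 var, f$max))
        sprintf("  FILTER(%s)", paste(parts, collapse = " && "))
      })
  }
  body <- character(0)
  if (query$dialect == "light") {
    body <- c(body, sprintf("  ?stmt a %s .", .sparql_term(query$type_iri)))
  } else {
    body <- c(body,
      sprintf("  ?stmt a %s .", .sparql_term(query$type_iri)),
      sprintf("  ?stmt %s ?version .", .sparql_term(vocab$has_version)),
      sprintf("  ?version %s ?vn .", .sparql_term(vocab$version_number)),
      sprintf("  FILTER NOT EXISTS { ?stmt %s ?del } .",
              .sparql_term(vocab$deleted_at)),
      sprintf("  FILTER NOT EXISTS { ?version %s ?vdel } .",
              .sparql_term(vocab$deleted_at)),
      sprintf(paste0("  FILTER NOT EXISTS { ?stmt %s ?v2 . ?v2 %s ?vn2 .",
                     " FILTER NOT EXISTS { ?v2 %s ?v2del } FILTER(?vn2 > ?vn) }"),
              .sparql_term(vocab$has_version),
              .sparql_term(vocab$version_number),
              .sparql_term(vocab$deleted_at)))
  }
  for (role in names(query$filters)) {
    i <- i + 1L
    var <- paste0("?v", i)
    body <- c(body, slot_pattern(role, var),
              filter_clause(query$filters[[role]], var))
  }
  sel <- if (query$dialect == "light") "SELECT DISTINCT ?stmt"
         else "SELECT DISTINCT ?stmt ?version"
  paste0("PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>\n",
         sel, " WHERE {\n", paste(body, collapse = "\n"), "\n}\n")
}

## ---- statement store -------------------------------------------------------

#' An in-memory statement store
#'
#' Holds anchors of registered statement types and exposes the queryable
#' union graph. No database backend: serialization to TriG is the
#' persistence format.
#' @param registry a [schema_registry()]
#' @return a `rosetta_store`
#' @export
rosetta_store <- function(registry) {
  structure(list(registry = registry, anchors = list()),
            class = "rosetta_store")
}

#' @rdname rosetta_store
#' @param store a `rosetta_store`
#' @param anchor a `rosetta_anchor`
#' @export
store_add <- function(store, anchor) {
  store$anchors[[anchor$anchor_iri]] <- anchor
  store
}

#' Union full-dialect graph of all anchors in a store
#' @param store a `rosetta_store`
#' @return a `rosetta_graph`
#' @export
store_graph <- function(store) {
  gs <- lapply(store$anchors, to_full_graph)
  if (!length(gs)) return(rdf_graph())
  g_canonical(do.call(g_union, unname(gs)))
}

.filter_matches <- function(f, b, graph_df) {
  if (inherits(b, "rosetta_resource")) {
    switch(f$kind,
      resource = identical(b$iri, f$iri),
      class = {
        admissible <- .subclass_closure(graph_df, f$iri)
        types <- unique(c(b$class_iri,
                          graph_df$object[graph_df$subject == b$iri &
                                            graph_df$predicate == RDF_TYPE]))
        any(types %in% admissible)
      },
      FALSE)
  } else {
    switch(f$kind,
      literal = identical(b$lexical, f$value),
      range = {
        num <- suppressWarnings(as.numeric(b$lexical))
        !is.na(num) && num >= f$min && num <= f$max
      },
      FALSE)
  }
}

#' Evaluate a slot query over a store
#'
#' Walks the store's union RDF graph: resolves each anchor of the queried
#' type to its current non-deleted version and keeps those whose bindings
#' satisfy every filter.
#' @param store a `rosetta_store`
#' @param query a `rosetta_query`
#' @return character vector of matching anchor IRIs (sorted)
#' @export
run_slot_query <- function(store, query) {
  gdf <- as.data.frame(store_graph(store))
  out <- character(0)
  for (anchor in store$anchors) {
    if (anchor$type_iri != query$type_iri) next
    if (.anchor_deleted(anchor)) next
    cur <- tryCatch(resolve_current(anchor), error = function(e) NULL)
    if (is.null(cur)) next
    st <- cur$statement
    ok <- TRUE
    for (role in names(query$filters)) {
      f <- query$filters[[role]]
      bs <- if (role == "subject") st$subject_bindings
            else st$bindings[[role]] %||% list()
      if (!length(bs) ||
          !any(vapply(bs, function(b) .filter_matches(f, b, gdf), logical(1)))) {
        ok <- FALSE; break
      }
    }
    if (ok) out <- c(out, anchor$anchor_iri)
  }
  sort(out)
}

#' Facet counts for a statement type
#'
#' One facet per subject/object position of the type's schema; counts the
#' values of the current version of each non-deleted anchor. Resources
#' count by label (falling back to IRI), literals by lexical form;
#' multi-valued positions contribute each value once per statement.
#' @param store a `rosetta_store`
#' @param type_iri statement type
#' @return named list: role -> named integer vector (value -> count)
#' @export
facet_counts <- function(store, type_iri) {
  schema <- store$registry[[type_iri]]
  if (is.null(schema)) stop("unknown statement type: ", type_iri)
  facets <- list()
  bump <- function(role, key) {
    tab <- facets[[role]] %||% integer(0)
    tab[key] <- (if (key %in% names(tab)) tab[[key]] else 0L) + 1L
    facets[[role]] <<- tab
  }
  for (anchor in store$anchors) {
    if (anchor$type_iri != type_iri || .anchor_deleted(anchor)) next
    cur <- tryCatch(resolve_current(anchor), error = function(e) NULL)
    if (is.null(cur)) next
    st <- cur$statement
    key_of <- function(b) if (inherits(b, "rosetta_resource"))
      b$label %||% b$iri else b$lexical
    for (b in st$subject_bindings) bump("subject", key_of(b))
    for (role in names(st$bindings))
      for (b in st$bindings[[role]]) bump(role, key_of(b))
  }
  facets
}
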