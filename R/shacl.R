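#' SHACL shape generation and validation
#'
#' Each statement type yields one node shape per dialect. The shape IRI is
#' the schema IRI, so the has-data-schema property of a statement resolves
#' to the very shape its graph must conform to. Validation implements the
#' SHACL core subset the generator emits: min/max count, datatype, class
#' (with rdfs:subClassOf closure over the data graph -- no reasoner is
#' invoked, subclass hierarchies must be asserted in the data), pattern,
#' numeric range, node kind, and qualified value shapes for the
#' position-instance indirection of the full dialect.
#' @name shapes
NULL

SH <- function(x) paste0("http://www.w3.org/ns/shacl#", x)

.prop_shape <- function(role, path, min_count, max_count, constraint,
                        via_class = NULL, alt_paths = NULL) {
  list(role = role, path = path, min_count = min_count,
       max_count = max_count, constraint = constraint,
       via_class = via_class, alt_paths = alt_paths)
}

#' Generate the SHACL shape bundle for a statement type
#'
#' Required positions get minCount 1, optional ones minCount 0; finite
#' max_values becomes maxCount; resource constraints become sh:class
#' (instances of the class or its subclasses), literal constraints become
#' sh:datatype plus optional sh:pattern and numeric range. Light-dialect
#' shapes target the statement class and use the numbered position
#' properties as paths; full-dialect shapes target the objects of
#' has-version triples and constrain position instances through qualified
#' value shapes.
#'
#' @param schema a `rosetta_schema`
#' @param dialect "light" or "full"
#' @param closed when TRUE the shape also flags predicates outside the
#'   metamodel (off by default: optional adjuncts may be added to a type
#'   later without breaking older data)
#' @return a `rosetta_shape`
#' @export
generate_shape <- function(schema, dialect = c("light", "full"),
                           closed = FALSE) {
  dialect <- match.arg(dialect)
  vocab <- rosetta_vocabulary(schema$base)
  shapes <- list()
  if (dialect == "light") {
    shapes[[1]] <- .prop_shape("subject", vocab$subject, 1L, NULL,
                               schema$subject$constraint)
    for (p in schema$objects)
      shapes[[length(shapes) + 1L]] <- .prop_shape(
        p$role,
        position_property(vocab, p$required, p$constraint$kind == "literal",
                          p$index),
        if (p$required) 1L else 0L,
        if (is.finite(p$max_values)) as.integer(p$max_values) else NULL,
        p$constraint)
  } else {
    shapes[[1]] <- .prop_shape("subject", vocab$subject, 1L, NULL,
                               schema$subject$constraint,
                               via_class = vocab$subject_position_class)
    for (p in schema$objects) {
      link <- if (p$required) vocab$required_object_position
              else vocab$optional_object_position
      shapes[[length(shapes) + 1L]] <- .prop_shape(
        p$role, link,
        if (p$required) 1L else 0L,
        if (is.finite(p$max_values)) as.integer(p$max_values) else NULL,
        p$constraint,
        via_class = position_class_iri(schema, p$role),
        alt_paths = vocab$has_object_position)
    }
  }
  structure(list(shape_iri = schema$schema_iri,
                 target_class = schema$type_iri, dialect = dialect,
                 closed = closed, prop_shapes = shapes, vocab = vocab,
                 schema = schema),
            class = "rosetta_shape")
}

#' The shape bundle as a SHACL RDF graph
#' @param bundle a `rosetta_shape`
#' @return a `rosetta_graph` (serializable with [write_turtle()])
#' @export
shape_graph <- function(bundle) {
  vocab <- bundle$vocab
  g <- rdf_graph(prefixes = c(default_prefixes(), rosetta = vocab$ns))
  s <- bundle$shape_iri
  g <- g_add(g, triple(s, RDF_TYPE, SH("NodeShape")))
  g <- if (bundle$dialect == "light")
    g_add(g, triple(s, SH("targetClass"), bundle$target_class))
  else g_add(g, triple(s, SH("targetObjectsOf"), vocab$has_version))
  if (bundle$closed)
    g <- g_add(g, lit_triple(s, SH("closed"), "true", xsd_iri("boolean")))
  value_constraint_rows <- function(node, ck) {
    rows <- list()
    if (ck$kind == "resource") {
      rows[[1]] <- triple(node, SH("class"), ck$value_class)
      rows[[2]] <- triple(node, SH("nodeKind"), SH("IRI"))
    } else {
      rows[[1]] <- triple(node, SH("datatype"), ck$datatype_iri)
      rows[[2]] <- triple(node, SH("nodeKind"), SH("Literal"))
      if (!is.null(ck$pattern))
        rows[[length(rows) + 1L]] <- lit_triple(node, SH("pattern"), ck$pattern)
      if (!is.null(ck$min))
        rows[[length(rows) + 1L]] <- lit_triple(node, SH("minInclusive"),
          format(ck$min, scientific = FALSE), xsd_iri("decimal"))
      if (!is.null(ck$max))
        rows[[length(rows) + 1L]] <- lit_triple(node, SH("maxInclusive"),
          format(ck$max, scientific = FALSE), xsd_iri("decimal"))
    }
    do.call(rbind, rows)
  }
  for (ps in bundle$prop_shapes) {
    pnode <- paste0(s, "-prop-", iri_slug(ps$role))
    g <- g_add(g, triple(s, SH("property"), pnode),
               triple(pnode, RDF_TYPE, SH("PropertyShape")),
               triple(pnode, SH("path"), ps$path))
    if (is.null(ps$via_class)) {
      g <- g_add(g, value_constraint_rows(pnode, ps$constraint))
      if (!is.null(ps$min_count) && ps$min_count > 0L)
        g <- g_add(g, lit_triple(pnode, SH("minCount"),
                                 as.character(ps$min_count), xsd_iri("integer")))
      if (!is.null(ps$max_count))
        g <- g_add(g, lit_triple(pnode, SH("maxCount"),
                                 as.character(ps$max_count), xsd_iri("integer")))
    } else {
      qnode <- paste0(pnode, "-qualified")
      vnode <- paste0(pnode, "-value")
      g <- g_add(g, triple(pnode, SH("qualifiedValueShape"), qnode),
                 triple(qnode, SH("class"), ps$via_class),
                 triple(qnode, SH("property"), vnode),
                 triple(vnode, SH("path"), vocab$value),
                 lit_triple(vnode, SH("minCount"), "1", xsd_iri("integer")),
                 value_constraint_rows(vnode, ps$constraint))
      if (!is.null(ps$min_count) && ps$min_count > 0L)
        g <- g_add(g, lit_triple(pnode, SH("qualifiedMinCount"),
                                 as.character(ps$min_count), xsd_iri("integer")))
      if (!is.null(ps$max_count))
        g <- g_add(g, lit_triple(pnode, SH("qualifiedMaxCount"),
                                 as.character(ps$max_count), xsd_iri("integer")))
    }
  }
  g_canonical(g)
}

.subclass_closure <- function(df, class_iri) {
  out <- class_iri
  repeat {
    subs <- unique(df$subject[df$predicate == RDFS_SUBCLASS &
                                df$object %in% out])
    new <- setdiff(subs, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

.value_violations <- function(df, row, ck, focus, path, role) {
  mk <- function(rule, msg)
    data.frame(focus = focus, path = path, rule = rule, message = msg,
               stringsAsFactors = FALSE)
  out <- list()
  if (ck$kind == "resource") {
    if (!row$object_is_iri)
      return(mk("nodeKind", paste0(role, ": expected a resource, found a literal")))
    admissible <- .subclass_closure(df, ck$value_class)
    types <- df$object[df$subject == row$object & df$predicate == RDF_TYPE]
    if (!any(types %in% admissible))
      out[[length(out) + 1L]] <- mk("class",
        paste0(role, ": ", row$object, " is not an instance of ",
               ck$value_class, " or a subclass"))
  } else {
    if (row$object_is_iri)
      return(mk("nodeKind", paste0(role, ": expected a literal, found a resource")))
    if (!identical(row$datatype, ck$datatype_iri))
      out[[length(out) + 1L]] <- mk("datatype",
        paste0(role, ": datatype ", row$datatype, " does not match ",
               ck$datatype_iri))
    else if (!lexical_valid(row$object, ck$datatype_iri))
      out[[length(out) + 1L]] <- mk("datatype",
        paste0(role, ": \"", row$object, "\" is not a valid lexical form"))
    if (!is.null(ck$pattern) && !grepl(ck$pattern, row$object))
      out[[length(out) + 1L]] <- mk("pattern",
        paste0(role, ": \"", row$object, "\" does not match ", ck$pattern))
    num <- suppressWarnings(as.numeric(row$object))
    if (!is.null(ck$min) && !is.na(num) && num < ck$min)
      out[[length(out) + 1L]] <- mk("minInclusive",
        paste0(role, ": ", row$object, " < ", ck$min))
    if (!is.null(ck$max) && !is.na(num) && num > ck$max)
      out[[length(out) + 1L]] <- mk("maxInclusive",
        paste0(role, ": ", row$object, " > ", ck$max))
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Validate a statement graph against a shape bundle
#'
#' @param graph a `rosetta_graph` (light or full dialect, matching the
#'   bundle)
#' @param bundle a `rosetta_shape` from [generate_shape()]
#' @return list with `conforms` (logical) and `violations` (data frame with
#'   columns `focus`, `path`, `rule`, `message`)
#' @export
validate_statement <- function(graph, bundle) {
  if (!inherits(bundle, "rosetta_shape") || is.null(bundle$prop_shapes))
    stop("malformed shape bundle")
  df <- as.data.frame(graph)
  vocab <- bundle$vocab
  acc <- new.env(parent = emptyenv())
  acc$v <- list()
  add <- function(x) if (!is.null(x)) acc$v[[length(acc$v) + 1L]] <- x
  mk <- function(focus, path, rule, msg)
    data.frame(focus = focus, path = path, rule = rule, message = msg,
               stringsAsFactors = FALSE)
  focus_nodes <- if (bundle$dialect == "light") {
    unique(df$subject[df$predicate == RDF_TYPE &
                        df$object == bundle$target_class &
                        !df$subject %in% df$object[df$predicate == vocab$has_version]])
  } else unique(df$object[df$predicate == vocab$has_version])
  for (focus in focus_nodes) {
    own <- df[df$subject == focus, , drop = FALSE]
    for (ps in bundle$prop_shapes) {
      if (is.null(ps$via_class)) {
        rows <- own[own$predicate == ps$path, , drop = FALSE]
        n <- nrow(rows)
        if (!is.null(ps$min_count) && n < ps$min_count)
          add(mk(focus, ps$path, "minCount",
                 paste0(ps$role, ": ", n, " value(s), minimum ", ps$min_count)))
        if (!is.null(ps$max_count) && n > ps$max_count)
          add(mk(focus, ps$path, "maxCount",
                 paste0(ps$role, ": ", n, " value(s), maximum ", ps$max_count)))
        for (i in seq_len(n))
          add(.value_violations(df, rows[i, ], ps$constraint, focus, ps$path,
                                ps$role))
      } else {
        link_rows <- own[own$predicate %in% c(ps$path, ps$alt_paths), ,
                         drop = FALSE]
        is_inst <- vapply(link_rows$object, function(node)
          ps$via_class %in% df$object[df$subject == node &
                                        df$predicate == RDF_TYPE],
          logical(1))
        insts <- link_rows$object[is_inst]
        n <- length(insts)
        if (!is.null(ps$min_count) && n < ps$min_count)
          add(mk(focus, ps$path, "qualifiedMinCount",
                 paste0(ps$role, ": ", n, " position instance(s), minimum ",
                        ps$min_count)))
        if (!is.null(ps$max_count) && n > ps$max_count)
          add(mk(focus, ps$path, "qualifiedMaxCount",
                 paste0(ps$role, ": ", n, " position instance(s), maximum ",
                        ps$max_count)))
        for (node in insts) {
          vrows <- df[df$subject == node & df$predicate == vocab$value, ,
                      drop = FALSE]
          if (!nrow(vrows))
            add(mk(node, vocab$value, "minCount",
                   paste0(ps$role, ": position instance carries no value")))
          for (i in seq_len(nrow(vrows)))
            add(.value_violations(df, vrows[i, ], ps$constraint, node,
                                  vocab$value, ps$role))
        }
      }
    }
    if (bundle$closed) {
      allowed <- c(RDF_TYPE, unlist(vocab[names(vocab) != "ns"],
                                    use.names = FALSE),
                   vapply(bundle$prop_shapes, `[[`, character(1), "path"))
      candidates <- unique(own$predicate)
      candidates <- candidates[!grepl(.position_prop_regex(vocab), candidates) &
                                 !grepl("ObjectPosition[0-9]+Display$",
                                        candidates)]
      for (p in setdiff(candidates, allowed))
        add(mk(focus, p, "closed",
               paste0("predicate ", p, " is not allowed by the closed shape")))
    }
  }
  vdf <- if (length(acc$v)) do.call(rbind, acc$v)
         else data.frame(focus = character(), path = character(),
                         rule = character(), message = character(),
                         stringsAsFactors = FALSE)
  list(conforms = nrow(vdf) == 0L, violations = vdf)
}

#' Serialize a validation report
#' @param report result of [validate_statement()]
#' @param format "json" or "turtle"
#' @return serialized report text
#' @export
report_serialize <- function(report, format = c("json", "turtle")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(report, dataframe = "rows",
                                         auto_unbox = TRUE, pretty = TRUE)))
  g <- rdf_graph()
  r <- "urn:rosetta:validation-report"
  g <- g_add(g, triple(r, RDF_TYPE, SH("ValidationReport")),
             lit_triple(r, SH("conforms"),
                        if (report$conforms) "true" else "false",
                        xsd_iri("boolean")))
  v <- report$violations
  for (i in seq_len(nrow(v))) {
    node <- paste0(r, ":result:", i)
    g <- g_add(g, triple(r, SH("result"), node),
               triple(node, RDF_TYPE, SH("ValidationResult")),
               triple(node, SH("focusNode"), v$focus[i]),
               triple(node, SH("resultPath"), v$path[i]),
               lit_triple(node, SH("resultMessage"), v$message[i]))
  }
  write_turtle(g)
}
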