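#' Light dialect serialization
#'
#' The light metamodel links the statement instance directly to its subject
#' and objects via the numbered position property families, keeping the
#' graph as small as the sentence: the basic weight-measurement statement
#' takes three slot-linking triples (subject, value, unit) instead of the
#' five or six of observation-centric measurement schemata.
#' @name rdf-light
NULL

.metadata_triples <- function(node, prov, vocab, certainty = NULL,
                              graph = NA_character_) {
  rows <- list()
  addlit <- function(p, v, dt = xsd_iri("string"))
    rows[[length(rows) + 1L]] <<- lit_triple(node, p, v, dt, graph = graph)
  if (!is.null(prov$creator)) addlit(vocab$creator, prov$creator)
  if (!is.null(prov$created_at))
    addlit(vocab$created_at, prov$created_at, xsd_iri("dateTime"))
  if (!is.null(prov$author)) addlit(vocab$author, prov$author)
  if (!is.null(prov$extraction_method))
    addlit(vocab$extraction_method, prov$extraction_method)
  if (!is.null(prov$imported_from))
    addlit(vocab$imported_from, prov$imported_from)
  addlit(vocab$modifiable, if (prov$modifiable) "true" else "false",
         xsd_iri("boolean"))
  if (!is.null(prov$deleted_at))
    addlit(vocab$deleted_at, prov$deleted_at, xsd_iri("dateTime"))
  if (!is.null(prov$deleted_by)) addlit(vocab$deleted_by, prov$deleted_by)
  if (!is.null(certainty))
    addlit(vocab$certainty, format(certainty, scientific = FALSE),
           xsd_iri("decimal"))
  do.call(rbind, rows)
}

.resource_desc_triples <- function(b, graph = NA_character_) {
  rows <- triple(b$iri, RDF_TYPE, b$class_iri, graph = graph)
  if (!is.null(b$label))
    rows <- rbind(rows, lit_triple(b$iri, RDFS_LABEL, b$label, graph = graph))
  rows
}

#' Serialize a statement in the light dialect
#'
#' Emits one rdf:type triple into the statement class (plus one into the
#' negation class for negated statements), one subject triple per subject
#' binding, and per object binding one triple whose numbered predicate
#' encodes required/optional, resource/literal, and the position index.
#' Value resources additionally carry their class and label.
#'
#' @param statement a `rosetta_statement`
#' @param schema its `rosetta_schema`
#' @return a `rosetta_graph`
#' @export
to_light_graph <- function(statement, schema) {
  if (statement$type_iri != schema$type_iri)
    stop("statement type does not match schema")
  vocab <- rosetta_vocabulary(schema$base)
  s <- statement$statement_iri
  g <- rdf_graph(prefixes = c(default_prefixes(), rosetta = vocab$ns))
  g <- g_add(g, triple(s, RDF_TYPE, schema$type_iri))
  if (statement$negated)
    g <- g_add(g, triple(s, RDF_TYPE, vocab$negation_class))
  g <- g_add(g, triple(s, vocab$has_data_schema, schema$schema_iri))
  if (!is.null(statement$context_iri))
    g <- g_add(g, triple(s, vocab$has_context, statement$context_iri))
  for (b in statement$subject_bindings)
    g <- g_add(g, triple(s, vocab$subject, b$iri), .resource_desc_triples(b))
  for (role in names(statement$bindings)) {
    p <- schema_position(schema, role)
    pred <- position_property(vocab, p$required,
                              p$constraint$kind == "literal", p$index)
    vals <- statement$bindings[[role]]
    for (b in vals) {
      if (inherits(b, "rosetta_resource")) {
        g <- g_add(g, triple(s, pred, b$iri), .resource_desc_triples(b))
      } else {
        g <- g_add(g, lit_triple(s, pred, b$lexical, b$datatype_iri))
        if (!is.null(b$display)) {
          if (length(vals) > 1L)
            stop("display text on a multi-valued position (", role,
                 ") is not representable in the light dialect; use the full dialect")
          g <- g_add(g, lit_triple(
            s, position_display_property(vocab, p$required, TRUE, p$index),
            b$display))
        }
      }
    }
  }
  md <- .metadata_triples(s, statement$provenance, vocab,
                          certainty = statement$certainty)
  if (!is.null(md)) g <- g_add(g, md)
  g_canonical(g)
}

#' A registry of statement-type schemata
#' @param ... `rosetta_schema` objects
#' @return named list keyed by type IRI (class `rosetta_registry`)
#' @export
schema_registry <- function(...) {
  schemas <- list(...)
  if (length(schemas) == 1L && is.list(schemas[[1]]) &&
      !inherits(schemas[[1]], "rosetta_schema"))
    schemas <- schemas[[1]]
  out <- stats::setNames(schemas,
                         vapply(schemas, `[[`, character(1), "type_iri"))
  structure(out, class = "rosetta_registry")
}

.recover_literal_meta <- function(df, node, vocab) {
  prov <- provenance_metadata(
    creator = g_match(df, s = node, p = vocab$creator)$object[1] %|na|% "unknown",
    created_at = g_match(df, s = node, p = vocab$created_at)$object[1] %|na|%
      format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    author = .opt(g_match(df, s = node, p = vocab$author)$object[1]),
    extraction_method = .opt(g_match(df, s = node,
                                     p = vocab$extraction_method)$object[1]),
    imported_from = .opt(g_match(df, s = node,
                                 p = vocab$imported_from)$object[1]),
    modifiable = !identical(g_match(df, s = node,
                                    p = vocab$modifiable)$object[1], "false"),
    deleted_at = .opt(g_match(df, s = node, p = vocab$deleted_at)$object[1]),
    deleted_by = .opt(g_match(df, s = node, p = vocab$deleted_by)$object[1]))
  cert <- g_match(df, s = node, p = vocab$certainty)$object[1]
  list(prov = prov, certainty = if (!is.na(cert)) as.numeric(cert) else NULL)
}

.opt <- function(x) if (length(x) && !is.na(x)) x else NULL
`%|na|%` <- function(a, b) if (length(a) && !is.na(a)) a else b

.resource_from_graph <- function(df, iri, fallback_class) {
  classes <- g_match(df, s = iri, p = RDF_TYPE)$object
  resource_ref(iri,
               label = .opt(g_match(df, s = iri, p = RDFS_LABEL)$object[1]),
               class_iri = if (length(classes)) classes[1] else fallback_class)
}

#' Parse a light-dialect graph back into a statement
#'
#' Exact inverse of [to_light_graph()] up to order rank: the light dialect
#' carries no order property, so multiple values in one position are
#' assigned ranks by lexicographic sort of their serialized form (lossless
#' ordering requires the full dialect).
#'
#' @param graph a `rosetta_graph`
#' @param registry a [schema_registry()]
#' @return a `rosetta_statement`
#' @export
from_light_graph <- function(graph, registry) {
  df <- as.data.frame(graph)
  typed <- df[df$predicate == RDF_TYPE & df$object %in% names(registry), ,
              drop = FALSE]
  stmts <- unique(typed$subject)
  if (length(stmts) == 0L)
    stop("no statement with a type class resolvable in the registry")
  if (length(stmts) > 1L)
    stop("graph contains more than one statement instance")
  s <- stmts
  schema <- registry[[typed$object[typed$subject == s][1]]]
  vocab <- rosetta_vocabulary(schema$base)
  negated <- vocab$negation_class %in% g_match(df, s = s, p = RDF_TYPE)$object
  subj_iris <- sort(g_match(df, s = s, p = vocab$subject)$object)
  if (!length(subj_iris)) stop("graph carries no subject triple")
  subject <- lapply(subj_iris, .resource_from_graph, df = df,
                    fallback_class = schema$subject$constraint$value_class)
  bindings <- list()
  own <- df[df$subject == s, , drop = FALSE]
  for (i in seq_len(nrow(own))) {
    info <- parse_position_property(vocab, own$predicate[i])
    if (is.null(info)) next
    pos <- Filter(function(p) p$index == info$index, schema$objects)
    if (!length(pos))
      stop("predicate ", own$predicate[i], " has no matching position ",
           "(schema has ", length(schema$objects), " positions)")
    pos <- pos[[1]]
    if ((pos$constraint$kind == "literal") != info$literal ||
        pos$required != info$required)
      stop("predicate ", own$predicate[i],
           " disagrees with the schema's position ", pos$role)
    b <- if (info$literal) {
      disp <- g_match(df, s = s, p = position_display_property(
        vocab, info$required, TRUE, info$index))$object[1]
      typed_literal(own$object[i], datatype = own$datatype[i],
                    display = .opt(disp))
    } else .resource_from_graph(df, own$object[i], pos$constraint$value_class)
    bindings[[pos$role]] <- c(bindings[[pos$role]], list(b))
  }
  for (r in names(bindings)) {
    keys <- vapply(bindings[[r]], .binding_key, character(1))
    bindings[[r]] <- bindings[[r]][order(keys)]
  }
  meta <- .recover_literal_meta(df, s, vocab)
  ctx <- .opt(g_match(df, s = s, p = vocab$has_context)$object[1])
  create_statement(schema, subject, bindings, metadata = meta$prov,
                   negated = negated, certainty = meta$certainty,
                   context = ctx, statement_iri = s)
}

#' Count slot-linking triples of a statement
#'
#' Counts the triples whose subject is the statement IRI and whose predicate
#' is the subject property or a member of the numbered object-position
#' property families. rdf:type triples (and label/display/metadata triples)
#' are excluded, so the basic weight-measurement example counts three.
#'
#' @param graph a `rosetta_graph`
#' @param statement_iri the statement instance IRI
#' @param vocab a [rosetta_vocabulary()]
#' @return non-negative integer
#' @export
count_slot_triples <- function(graph, statement_iri,
                               vocab = rosetta_vocabulary()) {
  df <- g_match(graph, s = statement_iri)
  sum(df$predicate == vocab$subject |
        grepl(.position_prop_regex(vocab), df$predicate))
}
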