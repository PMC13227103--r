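#' Full dialect: anchors, versions, position instances
#'
#' The full metamodel reifies every syntactic position: subjects and objects
#' are linked to a statement version indirectly through position-instance
#' resources, each with its own IRI, order rank and optional display text or
#' boolean logical annotations. A version-independent anchor resource owns
#' the version chain; updates append versions and never touch earlier ones,
#' and deletion is soft (metadata stays accessible, per FAIR A2).
#' @name rdf-full
NULL

.now_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.new_version <- function(statement, number, creator, created_at, author,
                         certainty, identifier = NULL, base) {
  version_iri <- mint_iri("version", base)
  st <- statement
  st$statement_iri <- version_iri
  structure(list(version_iri = version_iri,
                 version_number = as.integer(number),
                 statement = st, creator = creator, created_at = created_at,
                 author = author, certainty = certainty,
                 identifier = identifier,
                 annotations = list(),
                 deleted_at = NULL, deleted_by = NULL),
            class = "rosetta_version")
}

#' Create an anchor with version 1
#'
#' @param statement a valid `rosetta_statement`
#' @param schema its schema
#' @param context_iri optional context (e.g. the publication the statement
#'   was taken from); defaults to the statement's own context
#' @return a `rosetta_anchor`
#' @export
create_anchor <- function(statement, schema, context_iri = NULL) {
  if (statement$type_iri != schema$type_iri)
    stop("statement type does not match schema")
  prov <- statement$provenance
  v1 <- .new_version(statement, 1L, creator = prov$creator,
                     created_at = prov$created_at, author = prov$author,
                     certainty = statement$certainty, base = schema$base)
  structure(list(anchor_iri = mint_iri("anchor", schema$base),
                 type_iri = schema$type_iri, schema_iri = schema$schema_iri,
                 context_iri = context_iri %||% statement$context_iri,
                 metadata = prov, versions = list(v1), schema = schema),
            class = "rosetta_anchor")
}

.anchor_deleted <- function(anchor) !is.null(anchor$metadata$deleted_at)

#' Append a new version to an anchor
#'
#' Rebuilds the current version's statement with the given replacement
#' bindings, re-validates it against the schema, and appends it as a new
#' version with number `max + 1`. Earlier versions are never modified.
#'
#' @param anchor a `rosetta_anchor`
#' @param new_bindings named list of role label -> binding(s) replacing the
#'   bindings of those roles; the special name "subject" replaces the
#'   subject bindings
#' @param editor who makes the edit
#' @param created_at timestamp of the edit
#' @param author optional author
#' @param certainty optional new certainty
#' @return the updated anchor
#' @export
update_statement <- function(anchor, new_bindings, editor = "unknown",
                             created_at = .now_iso(), author = NULL,
                             certainty = NULL) {
  if (.anchor_deleted(anchor))
    stop("cannot update a deleted anchor (deleted at ",
         anchor$metadata$deleted_at, ")", call. = FALSE)
  if (!anchor$metadata$modifiable)
    stop("anchor is not modifiable", call. = FALSE)
  cur <- resolve_current(anchor)
  st <- cur$statement
  subject <- if ("subject" %in% names(new_bindings))
    new_bindings[["subject"]] else st$subject_bindings
  bindings <- st$bindings
  for (r in setdiff(names(new_bindings), "subject")) bindings[[r]] <- new_bindings[[r]]
  new_st <- create_statement(anchor$schema, subject, bindings,
                             metadata = st$provenance, negated = st$negated,
                             certainty = certainty %||% cur$certainty,
                             context = st$context_iri)
  n <- max(vapply(anchor$versions, `[[`, integer(1), "version_number"))
  v <- .new_version(new_st, n + 1L, creator = editor,
                    created_at = created_at, author = author,
                    certainty = certainty %||% cur$certainty,
                    base = anchor$schema$base)
  anchor$versions <- c(anchor$versions, list(v))
  anchor
}

#' Resolve the current version of an anchor
#'
#' The anchor always resolves to the non-deleted version with the highest
#' version number.
#' @param anchor a `rosetta_anchor`
#' @return a `rosetta_version`
#' @export
resolve_current <- function(anchor) {
  if (.anchor_deleted(anchor))
    stop("anchor is deleted; only its metadata is accessible",
         call. = FALSE)
  alive <- Filter(function(v) is.null(v$deleted_at), anchor$versions)
  if (!length(alive))
    stop("all versions of this anchor are deleted", call. = FALSE)
  nums <- vapply(alive, `[[`, integer(1), "version_number")
  alive[[which.max(nums)]]
}

#' Soft-delete an anchor or a single version
#'
#' Marks the target deleted via deleted-at/deleted-by metadata. No content
#' is removed from the graph; retrieval keeps serving the provenance
#' metadata while suppressing the statement itself.
#'
#' @param anchor a `rosetta_anchor`
#' @param who user performing the deletion
#' @param when timestamp
#' @param version_number when given, delete only that version
#' @return the updated anchor
#' @export
soft_delete <- function(anchor, who, when = .now_iso(),
                        version_number = NULL) {
  if (is.null(version_number)) {
    if (.anchor_deleted(anchor))
      stop("anchor is already deleted", call. = FALSE)
    anchor$metadata$deleted_at <- when
    anchor$metadata$deleted_by <- who
    return(anchor)
  }
  idx <- which(vapply(anchor$versions, `[[`, integer(1),
                      "version_number") == version_number)
  if (!length(idx)) stop("no version numbered ", version_number)
  if (!is.null(anchor$versions[[idx]]$deleted_at))
    stop("version ", version_number, " is already deleted", call. = FALSE)
  anchor$versions[[idx]]$deleted_at <- when
  anchor$versions[[idx]]$deleted_by <- who
  anchor
}

#' Retrieve anchor metadata (always available, even after deletion)
#' @param anchor a `rosetta_anchor`
#' @return list of provenance fields plus IRIs
#' @export
anchor_metadata <- function(anchor) {
  c(list(anchor_iri = anchor$anchor_iri, type_iri = anchor$type_iri,
         schema_iri = anchor$schema_iri,
         n_versions = length(anchor$versions),
         deleted = .anchor_deleted(anchor)),
    unclass(anchor$metadata))
}

#' Retrieve anchor content (the current statement)
#'
#' For deleted anchors a deleted marker is returned instead of the
#' statement: the data are gone from view, the metadata are not.
#' @param anchor a `rosetta_anchor`
#' @return the current `rosetta_statement`, or a list with `deleted = TRUE`
#'   and the deletion metadata
#' @export
anchor_content <- function(anchor) {
  if (.anchor_deleted(anchor))
    return(list(deleted = TRUE, deleted_at = anchor$metadata$deleted_at,
                deleted_by = anchor$metadata$deleted_by))
  resolve_current(anchor)$statement
}

#' Per-position editing history
#'
#' One entry per version in version order; an entry is flagged as a change
#' when its value list differs from the previous version's.
#'
#' @param anchor a `rosetta_anchor`
#' @param role object role label, or "subject"
#' @return data frame with columns `version_number`, `values` (list column
#'   of canonical value strings), `creator`, `created_at`, `changed`
#' @export
position_history <- function(anchor, role) {
  if (role != "subject") schema_position(anchor$schema, role)  # errors if unknown
  rows <- lapply(anchor$versions, function(v) {
    bs <- if (role == "subject") v$statement$subject_bindings
          else v$statement$bindings[[role]]
    vals <- vapply(bs %||% list(), .binding_key, character(1))
    list(version_number = v$version_number, values = vals,
         creator = v$creator, created_at = v$created_at)
  })
  ord <- order(vapply(rows, `[[`, integer(1), "version_number"))
  rows <- rows[ord]
  changed <- logical(length(rows))
  for (i in seq_along(rows))
    changed[i] <- i > 1L && !identical(rows[[i]]$values, rows[[i - 1L]]$values)
  data.frame(version_number = vapply(rows, `[[`, integer(1), "version_number"),
             values = I(lapply(rows, `[[`, "values")),
             creator = vapply(rows, `[[`, character(1), "creator"),
             created_at = vapply(rows, `[[`, character(1), "created_at"),
             changed = changed, stringsAsFactors = FALSE)
}

#' Aggregated contributor metadata
#'
#' The union of the version-level creators and authors forms the
#' contributor metadata of the statement; the creation date of the highest
#' version is its last-update date.
#' @param anchor a `rosetta_anchor`
#' @return list with `contributors` (sorted unique) and `last_update`
#' @export
contributors <- function(anchor) {
  who <- unlist(lapply(anchor$versions, function(v) c(v$creator, v$author)))
  nums <- vapply(anchor$versions, `[[`, integer(1), "version_number")
  list(contributors = sort(unique(who[!is.na(who)])),
       last_update = anchor$versions[[which.max(nums)]]$created_at)
}

#' Annotate a logical property of a position
#'
#' Attaches a boolean annotation (e.g. transitivity of the PART position of
#' a has-part statement) to the position instances of a role in one
#' version. The set of property names is open; any identifier-shaped name
#' is accepted and minted in the rosetta namespace.
#'
#' @param anchor a `rosetta_anchor`
#' @param version_number which version to annotate
#' @param role object role label
#' @param property property name, e.g. "transitive"
#' @param flag logical value of the annotation
#' @return the updated anchor
#' @export
annotate_logical_property <- function(anchor, version_number, role, property,
                                      flag) {
  schema_position(anchor$schema, role)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", property))
    stop("invalid logical property name: ", property)
  idx <- which(vapply(anchor$versions, `[[`, integer(1),
                      "version_number") == version_number)
  if (!length(idx)) stop("no version numbered ", version_number)
  ann <- anchor$versions[[idx]]$annotations
  ann[[role]] <- utils::modifyList(ann[[role]] %||% list(),
                                   stats::setNames(list(isTRUE(flag)), property))
  anchor$versions[[idx]]$annotations <- ann
  anchor
}

## ---- RDF serialization ----------------------------------------------------

.pos_instance_iri <- function(version_iri, role, rank)
  paste0(version_iri, "/pos/", iri_slug(role), "/", rank)

.version_graph_rows <- function(anchor, v, vocab, simplified, gname) {
  schema <- anchor$schema
  st <- v$statement
  rows <- list()
  put <- function(x) rows[[length(rows) + 1L]] <<- x
  vi <- v$version_iri
  put(triple(vi, RDF_TYPE, schema$type_iri, graph = gname))
  if (st$negated) put(triple(vi, RDF_TYPE, vocab$negation_class, graph = gname))
  put(lit_triple(vi, vocab$version_number, as.character(v$version_number),
                 xsd_iri("integer"), graph = gname))
  if (!is.null(v$identifier))
    put(lit_triple(vi, vocab$version_identifier, v$identifier, graph = gname))
  if (!is.null(v$creator)) put(lit_triple(vi, vocab$creator, v$creator, graph = gname))
  if (!is.null(v$created_at))
    put(lit_triple(vi, vocab$created_at, v$created_at, xsd_iri("dateTime"),
                   graph = gname))
  if (!is.null(v$author)) put(lit_triple(vi, vocab$author, v$author, graph = gname))
  if (!is.null(v$certainty))
    put(lit_triple(vi, vocab$certainty,
                   format(v$certainty, scientific = FALSE),
                   xsd_iri("decimal"), graph = gname))
  if (!is.null(v$deleted_at)) {
    put(lit_triple(vi, vocab$deleted_at, v$deleted_at, xsd_iri("dateTime"),
                   graph = gname))
    put(lit_triple(vi, vocab$deleted_by, v$deleted_by, graph = gname))
  }
  emit_instance <- function(link_prop, pos_class, node, b, rank, ann = NULL) {
    put(triple(vi, link_prop, node, graph = gname))
    put(triple(node, RDF_TYPE, pos_class, graph = gname))
    put(lit_triple(node, vocab$order, as.character(rank), xsd_iri("integer"),
                   graph = gname))
    if (inherits(b, "rosetta_resource")) {
      put(triple(node, vocab$value, b$iri, graph = gname))
      put(.resource_desc_triples(b, graph = gname))
    } else {
      put(lit_triple(node, vocab$value, b$lexical, b$datatype_iri,
                     graph = gname))
      if (!is.null(b$display))
        put(lit_triple(node, vocab$display_text, b$display, graph = gname))
    }
    for (nm in names(ann %||% list()))
      put(lit_triple(node, paste0(vocab$ns, nm),
                     if (isTRUE(ann[[nm]])) "true" else "false",
                     xsd_iri("boolean"), graph = gname))
  }
  for (k in seq_along(st$subject_bindings))
    emit_instance(vocab$subject, vocab$subject_position_class,
                  .pos_instance_iri(vi, "subject", k),
                  st$subject_bindings[[k]], k)
  for (role in names(st$bindings)) {
    p <- schema_position(schema, role)
    link <- if (simplified) vocab$has_object_position
            else if (p$required) vocab$required_object_position
            else vocab$optional_object_position
    for (k in seq_along(st$bindings[[role]]))
      emit_instance(link, position_class_iri(schema, role),
                    .pos_instance_iri(vi, role, k),
                    st$bindings[[role]][[k]], k, ann = v$annotations[[role]])
  }
  do.call(rbind, rows)
}

#' Serialize an anchor with all its versions
#'
#' Anchor-level triples live in the default graph; each version's subgraph
#' is placed in a named graph whose IRI is the version IRI, so
#' [write_trig()] emits one named graph per version and [write_turtle()]
#' needs `flatten = TRUE`.
#'
#' @param anchor a `rosetta_anchor`
#' @param simplified use the single has-object-position property instead of
#'   the required/optional pair
#' @param flatten drop named-graph assignment (for Turtle output)
#' @return a `rosetta_graph`
#' @export
to_full_graph <- function(anchor, simplified = FALSE, flatten = FALSE) {
  vocab <- rosetta_vocabulary(anchor$schema$base)
  a <- anchor$anchor_iri
  g <- rdf_graph(prefixes = c(default_prefixes(), rosetta = vocab$ns))
  g <- g_add(g, triple(a, RDF_TYPE, anchor$type_iri),
             triple(a, vocab$has_data_schema, anchor$schema_iri))
  if (!is.null(anchor$context_iri))
    g <- g_add(g, triple(a, vocab$has_context, anchor$context_iri),
               triple(anchor$context_iri, vocab$has_statement, a))
  md <- .metadata_triples(a, anchor$metadata, vocab)
  if (!is.null(md)) g <- g_add(g, md)
  for (v in anchor$versions) {
    g <- g_add(g, triple(a, vocab$has_version, v$version_iri))
    g <- g_add(g, .version_graph_rows(anchor, v, vocab, simplified,
                                      gname = v$version_iri))
  }
  if (flatten) g$graph <- NA_character_
  g_canonical(g)
}

.parse_version <- function(df, vi, anchor_schema, vocab, registry) {
  schema <- anchor_schema
  simpl_props <- c(vocab$required_object_position,
                   vocab$optional_object_position, vocab$has_object_position)
  cls_to_role <- stats::setNames(
    c("subject", schema_roles(schema)),
    c(vocab$subject_position_class,
      vapply(schema_roles(schema), position_class_iri, character(1),
             schema = schema)))
  inst_rows <- df[df$subject == vi &
                    df$predicate %in% c(vocab$subject, simpl_props), ,
                  drop = FALSE]
  subj <- list(); bindings <- list(); ann <- list()
  for (node in inst_rows$object) {
    ndf <- df[df$subject == node, , drop = FALSE]
    cls <- ndf$object[ndf$predicate == RDF_TYPE]
    role <- cls_to_role[cls[cls %in% names(cls_to_role)][1]]
    if (is.na(role)) stop("position instance ", node, " has no known position class")
    vrow <- ndf[ndf$predicate == vocab$value, , drop = FALSE]
    if (!nrow(vrow))
      stop("dangling position instance without a value: ", node)
    rank <- as.integer(ndf$object[ndf$predicate == vocab$order][1])
    b <- if (vrow$object_is_iri[1]) {
      fb <- if (role == "subject") schema$subject$constraint$value_class
            else schema_position(schema, role)$constraint$value_class
      .resource_from_graph(df, vrow$object[1], fb)
    } else {
      typed_literal(vrow$object[1], datatype = vrow$datatype[1],
                    display = .opt(ndf$object[ndf$predicate == vocab$display_text][1]))
    }
    entry <- list(rank = rank %|na|% 1L, b = b)
    if (role == "subject") subj[[length(subj) + 1L]] <- entry
    else bindings[[role]] <- c(bindings[[role]], list(entry))
    for (i in seq_len(nrow(ndf))) {
      p <- ndf$predicate[i]
      if (startsWith(p, vocab$ns) &&
          !p %in% c(vocab$value, vocab$order, vocab$display_text) &&
          identical(ndf$datatype[i], xsd_iri("boolean")))
        ann[[role]][[sub(vocab$ns, "", p, fixed = TRUE)]] <-
          ndf$object[i] == "true"
    }
  }
  by_rank <- function(entries)
    lapply(entries[order(vapply(entries, `[[`, integer(1), "rank"))], `[[`, "b")
  subj <- by_rank(subj)
  bindings <- lapply(bindings, by_rank)
  own <- function(p) .opt(df$object[df$subject == vi & df$predicate == p][1])
  cert <- own(vocab$certainty)
  st <- create_statement(
    schema, subj, bindings,
    metadata = provenance_metadata(creator = own(vocab$creator) %||% "unknown",
                                   created_at = own(vocab$created_at) %||% .now_iso(),
                                   author = own(vocab$author)),
    negated = vocab$negation_class %in%
      df$object[df$subject == vi & df$predicate == RDF_TYPE],
    certainty = if (!is.null(cert)) as.numeric(cert) else NULL,
    statement_iri = vi)
  structure(list(version_iri = vi,
                 version_number = as.integer(own(vocab$version_number)),
                 statement = st, creator = own(vocab$creator) %||% "unknown",
                 created_at = own(vocab$created_at) %||% .now_iso(),
                 author = own(vocab$author),
                 certainty = if (!is.null(cert)) as.numeric(cert) else NULL,
                 identifier = own(vocab$version_identifier),
                 annotations = ann,
                 deleted_at = own(vocab$deleted_at),
                 deleted_by = own(vocab$deleted_by)),
            class = "rosetta_version")
}

#' Parse a full-dialect graph back into anchors
#'
#' Lossless inverse of [to_full_graph()], including order ranks, negation,
#' soft-delete markers and logical annotations.
#'
#' @param graph a `rosetta_graph`
#' @param registry a [schema_registry()]
#' @return a single `rosetta_anchor`, or a list of them when the graph holds
#'   several
#' @export
from_full_graph <- function(graph, registry) {
  df <- as.data.frame(graph)
  bases <- unique(vapply(unclass(registry), `[[`, character(1), "base"))
  vocab <- rosetta_vocabulary(bases[1])
  anchors_iris <- unique(df$subject[df$predicate == vocab$has_version])
  if (!length(anchors_iris)) stop("graph contains no anchor (no has-version triple)")
  out <- lapply(anchors_iris, function(a) {
    ty <- df$object[df$subject == a & df$predicate == RDF_TYPE]
    ty <- ty[ty %in% names(registry)]
    if (!length(ty)) stop("anchor ", a, " has no type class resolvable in the registry")
    schema <- registry[[ty[1]]]
    own <- function(p) .opt(df$object[df$subject == a & df$predicate == p][1])
    prov <- provenance_metadata(
      creator = own(vocab$creator) %||% "unknown",
      created_at = own(vocab$created_at) %||% .now_iso(),
      author = own(vocab$author),
      extraction_method = own(vocab$extraction_method),
      imported_from = own(vocab$imported_from),
      modifiable = !identical(own(vocab$modifiable), "false"),
      deleted_at = own(vocab$deleted_at), deleted_by = own(vocab$deleted_by))
    v_iris <- df$object[df$subject == a & df$predicate == vocab$has_version]
    versions <- lapply(v_iris, .parse_version, df = df,
                       anchor_schema = schema, vocab = vocab,
                       registry = registry)
    versions <- versions[order(vapply(versions, `[[`, integer(1),
                                      "version_number"))]
    structure(list(anchor_iri = a, type_iri = schema$type_iri,
                   schema_iri = own(vocab$has_data_schema) %||% schema$schema_iri,
                   context_iri = own(vocab$has_context),
                   metadata = prov, versions = versions, schema = schema),
              class = "rosetta_anchor")
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Compare two anchors for semantic equality
#' @param a,b `rosetta_anchor` objects
#' @return logical
#' @export
anchors_equal <- function(a, b) {
  if (!identical(a$anchor_iri, b$anchor_iri) ||
      !identical(a$type_iri, b$type_iri) ||
      length(a$versions) != length(b$versions)) return(FALSE)
  for (i in seq_along(a$versions)) {
    va <- a$versions[[i]]; vb <- b$versions[[i]]
    if (va$version_number != vb$version_number ||
        !statements_equal(va$statement, vb$statement) ||
        !identical(va$deleted_at %||% NA_character_,
                   vb$deleted_at %||% NA_character_) ||
        !identical(va$annotations[sort(names(va$annotations))],
                   vb$annotations[sort(names(vb$annotations))]))
      return(FALSE)
  }
  TRUE
}

#' @export
print.rosetta_anchor <- function(x, ...) {
  cat("<rosetta_anchor> ", x$anchor_iri, "\n  type: ", x$type_iri,
      "\n  versions: ", length(x$versions), sep = "")
  if (.anchor_deleted(x)) cat("  [deleted]")
  cat("\n")
  invisible(x)
}
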