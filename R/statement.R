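#' Token statements
#'
#' A statement record is one token statement: bindings of the schema's
#' positions to resource references or typed literals, plus statement-level
#' negation, certainty, context and provenance.
#' @name statement-model
NULL

#' Reference to a resource (named individual)
#'
#' @param iri the resource GUPRI
#' @param label human-readable label
#' @param class_iri class the individual instantiates; defaults, at
#'   statement-creation time, to the constraint class of the position the
#'   reference is bound to
#' @return a `rosetta_resource`
#' @export
resource_ref <- function(iri, label = NULL, class_iri = NULL) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  structure(list(iri = iri, label = label, class_iri = class_iri),
            class = "rosetta_resource")
}

#' Typed literal value
#'
#' @param lexical lexical form, stored verbatim (rendering never reformats
#'   numbers)
#' @param datatype editor type name (see [xsd_datatype_for()]) or an XSD
#'   datatype IRI
#' @param display optional display text carried alongside the typed value
#'   (e.g. "21st of April 2023" next to "2023-04-21")
#' @return a `rosetta_literal`
#' @export
typed_literal <- function(lexical, datatype = "text", display = NULL) {
  dt_iri <- if (grepl("^https?://", datatype)) datatype
            else xsd_datatype_for(datatype)
  structure(list(lexical = as.character(lexical), datatype_iri = dt_iri,
                 display = display), class = "rosetta_literal")
}

#' Check a lexical form against an XSD datatype
#' @param lexical lexical form
#' @param datatype_iri XSD datatype IRI
#' @return logical
#' @export
lexical_valid <- function(lexical, datatype_iri) {
  name <- sub("^.*#", "", datatype_iri)
  pat <- switch(name,
    integer  = "^[+-]?[0-9]+$",
    decimal  = "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$",
    float    = "^([+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?|NaN|INF|-INF)$",
    double   = "^([+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?|NaN|INF|-INF)$",
    boolean  = "^(true|false|0|1)$",
    date     = "^-?[0-9]{4}-[0-9]{2}-[0-9]{2}(Z|[+-][0-9]{2}:[0-9]{2})?$",
    dateTime = "^-?[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?(Z|[+-][0-9]{2}:[0-9]{2})?$",
    anyURI   = "^\\S+$",
    string   = NULL,
    NULL)
  if (is.null(pat)) TRUE else grepl(pat, lexical)
}

#' Provenance metadata for a statement
#'
#' @param creator who created the record in the graph
#' @param created_at ISO-8601 timestamp string
#' @param author who asserted the statement (may differ from creator)
#' @param extraction_method e.g. "manual", "llm" when machine-extracted
#' @param imported_from source the statement was imported from, if any
#' @param modifiable whether users may edit the statement
#' @param deleted_at,deleted_by soft-delete marker; both present or both
#'   absent
#' @return a `rosetta_provenance`
#' @export
provenance_metadata <- function(creator = "unknown",
                                created_at = format(Sys.time(),
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                                author = NULL, extraction_method = NULL,
                                imported_from = NULL, modifiable = TRUE,
                                deleted_at = NULL, deleted_by = NULL) {
  if (is.null(deleted_at) != is.null(deleted_by))
    stop("deleted_at and deleted_by must both be present or both absent")
  structure(list(creator = creator, created_at = created_at, author = author,
                 extraction_method = extraction_method,
                 imported_from = imported_from, modifiable = isTRUE(modifiable),
                 deleted_at = deleted_at, deleted_by = deleted_by),
            class = "rosetta_provenance")
}

.as_binding_list <- function(x) {
  if (inherits(x, "rosetta_resource") || inherits(x, "rosetta_literal"))
    list(x)
  else if (is.list(x)) x
  else stop("bindings must be resource_ref()/typed_literal() or lists of them")
}

.check_binding <- function(b, pos, role) {
  ck <- pos$constraint
  if (ck$kind == "resource") {
    if (!inherits(b, "rosetta_resource"))
      stop("position ", role, " requires a resource, got a literal")
    if (is.null(b$class_iri)) b$class_iri <- ck$value_class
  } else {
    if (!inherits(b, "rosetta_literal"))
      stop("position ", role, " requires a literal, got a resource")
    if (b$datatype_iri != ck$datatype_iri)
      stop("position ", role, " requires datatype ", ck$datatype_iri,
           ", got ", b$datatype_iri)
    if (!lexical_valid(b$lexical, b$datatype_iri))
      stop("invalid lexical form for position ", role, ": \"", b$lexical,
           "\" is not a valid ", sub("^.*#", "", b$datatype_iri))
    if (!is.null(ck$pattern) && !grepl(ck$pattern, b$lexical))
      stop("position ", role, ": value \"", b$lexical,
           "\" does not match pattern ", ck$pattern)
    num <- suppressWarnings(as.numeric(b$lexical))
    if (!is.null(ck$min) && !is.na(num) && num < ck$min)
      stop("position ", role, ": value ", b$lexical, " below minimum ", ck$min)
    if (!is.null(ck$max) && !is.na(num) && num > ck$max)
      stop("position ", role, ": value ", b$lexical, " above maximum ", ck$max)
  }
  b
}

.validate_bindings <- function(schema, subject, bindings) {
  subject <- .as_binding_list(subject)
  if (!length(subject)) stop("missing required position: subject")
  subject <- lapply(subject, .check_binding, pos = schema$subject,
                    role = schema$subject$role)
  if (anyDuplicated(vapply(subject, .value_key, character(1))))
    stop("duplicate subject values are not representable in RDF")
  known <- schema_roles(schema)
  unknown <- setdiff(names(bindings), known)
  if (length(unknown))
    stop("unknown role label: ", paste(unknown, collapse = ", "))
  out <- list()
  for (p in schema$objects) {
    vals <- bindings[[p$role]]
    vals <- if (is.null(vals)) list() else .as_binding_list(vals)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (p$required && !length(vals))
      stop("missing required position: ", p$role)
    if (length(vals) > p$max_values)
      stop("position ", p$role, ": ", length(vals),
           " values exceed max_values = ", p$max_values)
    vals <- lapply(vals, .check_binding, pos = p, role = p$role)
    if (anyDuplicated(vapply(vals, .value_key, character(1))))
      stop("position ", p$role, ": duplicate values in one position are ",
           "not representable in RDF (triples are a set)")
    for (i in seq_along(vals)) attr(vals[[i]], "order_rank") <- i
    if (length(vals)) out[[p$role]] <- vals
  }
  for (i in seq_along(subject)) attr(subject[[i]], "order_rank") <- i
  list(subject = subject, bindings = out)
}

#' Create a token statement
#'
#' Applies every constraint and cardinality check of the schema, mints a
#' statement IRI, and assigns contiguous order ranks to multi-valued
#' positions.
#'
#' @param schema a `rosetta_schema`
#' @param subject one [resource_ref()] or a list of them
#' @param bindings named list: role label -> binding or list of bindings
#' @param metadata a [provenance_metadata()]
#' @param negated whether the statement is negated (classified into the
#'   negation class on serialization)
#' @param certainty optional decimal in [0, 1]
#' @param context optional IRI of the content the statement belongs to
#'   (e.g. a publication)
#' @param statement_iri optional pre-minted IRI
#' @return a `rosetta_statement`
#' @export
create_statement <- function(schema, subject, bindings = list(),
                             metadata = provenance_metadata(),
                             negated = FALSE, certainty = NULL,
                             context = NULL, statement_iri = NULL) {
  issues <- validate_type_schema(schema)
  if (nrow(issues))
    stop("schema is not valid: ", paste(issues$message, collapse = "; "))
  if (!is.null(certainty)) {
    certainty <- as.numeric(certainty)
    if (is.na(certainty) || certainty < 0 || certainty > 1)
      stop("certainty must be a decimal in [0, 1]")
  }
  v <- .validate_bindings(schema, subject, bindings)
  structure(list(
    statement_iri = statement_iri %||% mint_iri("statement", schema$base),
    type_iri = schema$type_iri,
    subject_bindings = v$subject,
    bindings = v$bindings,
    negated = isTRUE(negated),
    certainty = certainty,
    context_iri = context,
    provenance = metadata), class = "rosetta_statement")
}

.value_key <- function(b) {
  if (inherits(b, "rosetta_resource")) paste0("<", b$iri, ">")
  else paste0("\"", b$lexical, "\"^^", b$datatype_iri)
}

.binding_key <- function(b) {
  if (inherits(b, "rosetta_resource"))
    paste0("<", b$iri, ">|", b$label %||% "", "|", b$class_iri %||% "")
  else paste0("\"", b$lexical, "\"^^", b$datatype_iri, "|", b$display %||% "")
}

#' Compare two statements for semantic equality
#'
#' @param a,b `rosetta_statement` objects
#' @param ignore_order compare each position's values as a set (the light
#'   dialect does not preserve value order)
#' @param ignore_iri ignore the statement IRIs
#' @return logical
#' @export
statements_equal <- function(a, b, ignore_order = FALSE, ignore_iri = FALSE) {
  keyset <- function(bs) {
    k <- vapply(bs, .binding_key, character(1))
    if (ignore_order) sort(k) else k
  }
  if (!ignore_iri && !identical(a$statement_iri, b$statement_iri)) return(FALSE)
  if (!identical(a$type_iri, b$type_iri)) return(FALSE)
  if (!identical(keyset(a$subject_bindings), keyset(b$subject_bindings)))
    return(FALSE)
  if (!setequal(names(a$bindings), names(b$bindings))) return(FALSE)
  for (r in names(a$bindings))
    if (!identical(keyset(a$bindings[[r]]), keyset(b$bindings[[r]])))
      return(FALSE)
  identical(a$negated, b$negated) &&
    isTRUE(all.equal(a$certainty, b$certainty)) &&
    identical(a$context_iri %||% NA_character_, b$context_iri %||% NA_character_)
}

#' @export
print.rosetta_statement <- function(x, ...) {
  cat("<rosetta_statement> ", x$statement_iri, "\n  type: ", x$type_iri,
      "\n", sep = "")
  fmt <- function(b) if (inherits(b, "rosetta_resource"))
    paste0(b$label %||% b$iri, " <", b$iri, ">")
  else paste0("\"", b$lexical, "\"^^", sub("^.*#", "xsd:", b$datatype_iri))
  cat("  subject: ", paste(vapply(x$subject_bindings, fmt, character(1)),
                           collapse = "; "), "\n", sep = "")
  for (r in names(x$bindings))
    cat("  ", r, ": ", paste(vapply(x$bindings[[r]], fmt, character(1)),
                             collapse = "; "), "\n", sep = "")
  if (x$negated) cat("  [negated]\n")
  if (!is.null(x$certainty)) cat("  certainty:", x$certainty, "\n")
  invisible(x)
}
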