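#' Statement-type schemata
#'
#' A statement type mirrors the predicate--argument structure of one simple
#' English sentence: a verb, a subject position, and an ordered list of
#' object positions. Required positions are the verb's arguments, optional
#' ones its adjuncts. Every position carries a constraint: an ontology class
#' for resource slots, an XSD datatype (with optional pattern / numeric
#' range) for literal slots.
#' @name schema-model
NULL

.editor_types <- c(text = "string", URL = "anyURI", date = "date",
                   datetime = "dateTime", boolean = "boolean",
                   integer = "integer", decimal = "decimal", float = "float")

#' Map an editor input type to its XSD datatype IRI
#'
#' The input types offered by the statement-type editor map deterministically
#' onto XSD: text to string, URL to anyURI, date, datetime to dateTime,
#' boolean, integer, decimal and float to their XSD namesakes.
#' @param editor_type one of `r paste(names(.editor_types), collapse = ", ")`
#' @return XSD datatype IRI
#' @export
xsd_datatype_for <- function(editor_type) {
  if (!is.character(editor_type) || length(editor_type) != 1L ||
      !editor_type %in% names(.editor_types))
    stop("unknown editor type: ", paste(editor_type, collapse = ", "))
  xsd_iri(.editor_types[[editor_type]])
}

#' Slot constraint specification
#'
#' @param kind "resource" or "literal"
#' @param value_class for resource slots: IRI of the ontology class whose
#'   instances (including subclass instances) are admissible
#' @param datatype for literal slots: editor type name (see
#'   [xsd_datatype_for()])
#' @param pattern optional regular expression the lexical form must match
#' @param min,max optional numeric bounds for numeric datatypes
#' @return a `rosetta_constraint`
#' @export
constraint_spec <- function(kind = c("resource", "literal"), value_class = NULL,
                            datatype = NULL, pattern = NULL, min = NULL,
                            max = NULL) {
  kind <- match.arg(kind)
  if (kind == "resource") {
    if (is.null(value_class) || !is.null(datatype))
      stop("resource constraint requires value_class and no datatype")
    out <- list(kind = kind, value_class = value_class)
  } else {
    if (is.null(datatype) || !is.null(value_class))
      stop("literal constraint requires datatype and no value_class")
    out <- list(kind = kind, datatype = datatype,
                datatype_iri = xsd_datatype_for(datatype),
                pattern = pattern, min = min, max = max)
  }
  structure(out, class = "rosetta_constraint")
}

#' Position (slot) specification
#'
#' @param role thematic role label, unique within a schema (e.g. "QUALITY")
#' @param constraint a [constraint_spec()]
#' @param placeholder input-field placeholder text
#' @param pre,post pre-/postposition text shown around the slot in the
#'   dynamic label when the slot is non-empty
#' @param description longer help text for the position
#' @param required argument (TRUE) vs adjunct (FALSE)
#' @param max_values maximum number of values allowed (Inf = unbounded)
#' @return a `rosetta_position`
#' @export
position_spec <- function(role, constraint, placeholder = "", pre = "",
                          post = "", description = "", required = TRUE,
                          max_values = Inf) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            inherits(constraint, "rosetta_constraint"))
  if (!(is.numeric(max_values) && length(max_values) == 1L &&
        (is.infinite(max_values) || (max_values >= 1 && max_values == floor(max_values)))))
    stop("max_values must be a positive integer or Inf")
  structure(list(role = role, constraint = constraint,
                 placeholder = placeholder, pre = pre, post = post,
                 description = description, required = isTRUE(required),
                 max_values = max_values, index = NA_integer_),
            class = "rosetta_position")
}

#' Define a statement type
#'
#' Mints a statement-class IRI (slugged from the label) and a schema IRI
#' (the identifier of the derived shape, target of the has-data-schema
#' property), and indexes the object positions contiguously in the order
#' given.
#'
#' @param label verb/predicate display label of the statement class
#' @param description definition of the statement class
#' @param examples example natural-language sentences
#' @param subject_spec a [position_spec()] with a resource constraint
#' @param object_specs list of [position_spec()]; may be empty
#'   (intransitive verbs)
#' @param verb_text how the verb reads inside the dynamic label
#'   (defaults to `label`)
#' @param display_templates optional list of declared display templates (see
#'   [label_template()]); the first is the default
#' @param base namespace base IRI
#' @return a `rosetta_schema`
#' @export
define_statement_type <- function(label, description = "",
                                  examples = character(), subject_spec,
                                  object_specs = list(), verb_text = label,
                                  display_templates = list(),
                                  base = getOption("rosettastmt.base_iri",
                                                   "https://w3id.org/rosetta/")) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    stop("statement type label must be a non-empty string")
  if (subject_spec$constraint$kind != "resource")
    stop("subject position must have a resource constraint, got literal (",
         subject_spec$constraint$datatype, ")")
  roles <- vapply(object_specs, `[[`, character(1), "role")
  dup <- roles[duplicated(roles)]
  if (length(dup))
    stop("duplicate object position role label: ", paste(unique(dup), collapse = ", "))
  if (subject_spec$role %in% roles)
    stop("duplicate role label (shared with subject): ", subject_spec$role)
  subject_spec$index <- 0L
  for (i in seq_along(object_specs)) object_specs[[i]]$index <- i
  type_iri <- paste0(base, "class/", iri_slug(label), "-statement")
  structure(list(type_iri = type_iri,
                 schema_iri = paste0(type_iri, "-schema"),
                 label = label, verb_text = verb_text,
                 description = description, examples = examples,
                 subject = subject_spec, objects = object_specs,
                 display_templates = display_templates,
                 base = base),
            class = "rosetta_schema")
}

#' IRI of the per-type object-position class for a role
#' @param schema a `rosetta_schema`
#' @param role role label
#' @return class IRI
#' @export
position_class_iri <- function(schema, role) {
  paste0(schema$type_iri, "-position-", iri_slug(role))
}

#' Look up an object position by role
#' @param schema a `rosetta_schema`
#' @param role role label
#' @return a `rosetta_position` or error
#' @export
schema_position <- function(schema, role) {
  for (p in schema$objects) if (p$role == role) return(p)
  stop("unknown role label: ", role, " (schema '", schema$label, "')")
}

#' Role labels of a schema's object positions in index order
#' @param schema a `rosetta_schema`
#' @return character vector
#' @export
schema_roles <- function(schema) vapply(schema$objects, `[[`, character(1), "role")

#' Validate a statement-type schema
#'
#' Checks every structural invariant of the type model. Issues are returned
#' as data, never thrown.
#' @param schema a `rosetta_schema`
#' @return data frame with columns `field`, `rule`, `message`; zero rows iff
#'   the schema is well-formed
#' @export
validate_type_schema <- function(schema) {
  issues <- list()
  add <- function(field, rule, message)
    issues[[length(issues) + 1L]] <<- data.frame(field = field, rule = rule,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  if (!is.character(schema$label) || !nzchar(trimws(schema$label %||% "")))
    add("label", "non-empty", "statement type label must be non-empty")
  if (is.null(schema$subject))
    add("subject", "present", "subject position missing")
  else if (schema$subject$constraint$kind != "resource")
    add("subject", "subject-kind",
        "subject position constraint must be of resource kind")
  roles <- vapply(schema$objects, `[[`, character(1), "role")
  dup <- unique(roles[duplicated(roles)])
  for (d in dup)
    add(d, "duplicate-role", paste0("role label '", d, "' used more than once"))
  idx <- vapply(schema$objects, `[[`, integer(1), "index")
  if (length(idx) && !identical(as.integer(idx), seq_along(idx)))
    add("objects", "index-contiguous",
        "object position indices must form a contiguous 1..n sequence")
  for (p in schema$objects) {
    ck <- p$constraint
    if (ck$kind == "resource" && (is.null(ck$value_class) || !is.null(ck$datatype)))
      add(p$role, "constraint-kind", "resource constraint must carry value_class only")
    if (ck$kind == "literal" && (is.null(ck$datatype) || !is.null(ck$value_class)))
      add(p$role, "constraint-kind", "literal constraint must carry datatype only")
    if (!is.infinite(p$max_values) && p$max_values < 1)
      add(p$role, "max-values", "max_values must be >= 1")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(field = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Reorder the object positions of a schema
#'
#' @param schema a `rosetta_schema`
#' @param roles permutation of the existing object role labels, in the new
#'   rendering order
#' @return schema with indices reassigned 1..n; all other fields unchanged
#' @export
reorder_positions <- function(schema, roles) {
  old <- schema_roles(schema)
  if (!setequal(roles, old) || length(roles) != length(old))
    stop("roles must be a permutation of: ", paste(old, collapse = ", "))
  schema$objects <- lapply(seq_along(roles), function(i) {
    p <- schema_position(schema, roles[i])
    p$index <- i
    p
  })
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rosetta_schema <- function(x, ...) {
  cat("<rosetta_schema> ", x$label, "  (", length(x$objects),
      " object position(s))\n", sep = "")
  cat("  type:   ", x$type_iri, "\n  schema: ", x$schema_iri, "\n", sep = "")
  fmt <- function(p) sprintf("  %2d %-22s %-8s %s%s", p$index, p$role,
    p$constraint$kind,
    if (p$constraint$kind == "resource") p$constraint$value_class
    else p$constraint$datatype,
    if (p$required) "" else "  [adjunct]")
  cat(sprintf("   S %-22s %-8s %s", x$subject$role, "resource",
              x$subject$constraint$value_class), "\n")
  for (p in x$objects) cat(fmt(p), "\n")
  invisible(x)
}

## ---- persistence ----------------------------------------------------------

.constraint_to_list <- function(ck) {
  if (ck$kind == "resource") list(kind = "resource", class = ck$value_class)
  else {
    out <- list(kind = "literal", datatype = ck$datatype)
    if (!is.null(ck$pattern)) out$pattern <- ck$pattern
    if (!is.null(ck$min)) out$min <- ck$min
    if (!is.null(ck$max)) out$max <- ck$max
    out
  }
}

.position_to_list <- function(p) {
  out <- list(role = p$role, placeholder = p$placeholder, pre = p$pre,
              post = p$post, description = p$description,
              required = p$required,
              constraint = .constraint_to_list(p$constraint))
  if (!is.infinite(p$max_values)) out$max_values <- p$max_values
  out
}

#' Convert a schema to its plain-list document form
#' @param schema a `rosetta_schema`
#' @return list mirroring the statement-type definition file structure
#' @export
schema_to_list <- function(schema) {
  list(type_iri = schema$type_iri, schema_iri = schema$schema_iri,
       label = schema$label, verb_text = schema$verb_text,
       description = schema$description,
       examples = as.list(schema$examples),
       subject = .position_to_list(schema$subject),
       objects = lapply(schema$objects, .position_to_list),
       display_templates = lapply(schema$display_templates,
                                  template_to_list),
       base = schema$base)
}

.list_to_constraint <- function(x) {
  if (x$kind == "resource") constraint_spec("resource", value_class = x$class)
  else constraint_spec("literal", datatype = x$datatype, pattern = x$pattern,
                       min = x$min, max = x$max)
}

.list_to_position <- function(x) {
  position_spec(role = x$role, constraint = .list_to_constraint(x$constraint),
                placeholder = x$placeholder %||% "", pre = x$pre %||% "",
                post = x$post %||% "", description = x$description %||% "",
                required = x$required %||% TRUE,
                max_values = x$max_values %||% Inf)
}

#' Rebuild a schema from its document form
#' @param x list as produced by [schema_to_list()]
#' @return a `rosetta_schema`
#' @export
list_to_schema <- function(x) {
  sc <- define_statement_type(
    label = x$label, description = x$description %||% "",
    examples = unlist(x$examples) %||% character(),
    subject_spec = .list_to_position(x$subject),
    object_specs = lapply(x$objects, .list_to_position),
    verb_text = x$verb_text %||% x$label,
    display_templates = lapply(x$display_templates, list_to_template),
    base = x$base %||% getOption("rosettastmt.base_iri",
                                 "https://w3id.org/rosetta/"))
  if (!is.null(x$type_iri)) { sc$type_iri <- x$type_iri }
  if (!is.null(x$schema_iri)) { sc$schema_iri <- x$schema_iri }
  sc
}

#' Write / read a statement-type definition file
#'
#' The JSON form round-trips bit-exactly: `write_schema(read_schema(f))`
#' reproduces `f` byte for byte.
#' @param schema a `rosetta_schema`
#' @param path file path; format chosen by extension (.json / .yaml / .yml)
#' @return `path`, invisibly
#' @export
write_schema <- function(schema, path) {
  x <- schema_to_list(schema)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA,
                            null = "null")
    writeLines(txt, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(readLines(path, warn = FALSE),
                               simplifyVector = FALSE)
  list_to_schema(x)
}
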