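#' Dynamic labels and mind-map patterns
#'
#' A dynamic label maps the slots of a statement type into a sentence
#' template with per-slot pre- and postposition texts; empty optional slots
#' disappear together with their texts. A dynamic mind-map pattern renders
#' statements as labelled nodes around a predicate node, merging shared
#' resources across statements.
#' @name rendering
NULL

#' Template segment constructors
#'
#' A template is an ordered list of segments: fixed text, the verb, or a
#' slot (by role, "subject" for the subject position). Segments may belong
#' to a named group; a group is omitted entirely when any of its slots is
#' unbound (this is how e.g. a confidence-interval parenthetical, including
#' a repeated unit slot, vanishes as one unit).
#'
#' @param text fixed text
#' @param role slot role label ("subject" for the subject position)
#' @param pre,post texts shown before/after the slot value when non-empty
#' @param group optional group name
#' @return a template segment
#' @export
seg_text <- function(text, group = NULL)
  list(kind = "text", text = text, group = group)

#' @rdname seg_text
#' @export
seg_verb <- function(group = NULL) list(kind = "verb", group = group)

#' @rdname seg_text
#' @export
seg_slot <- function(role, pre = "", post = "", group = NULL)
  list(kind = "slot", role = role, pre = pre, post = post, group = group)

#' Construct a display template
#' @param segments list of segments ([seg_text()], [seg_verb()],
#'   [seg_slot()])
#' @param name template name
#' @return a `rosetta_template`
#' @export
label_template <- function(segments, name = "default") {
  structure(list(name = name, segments = segments),
            class = "rosetta_template")
}

#' @export
template_to_list <- function(tpl) {
  out <- unclass(tpl)
  out$segments <- lapply(out$segments, function(s) Filter(Negate(is.null), s))
  out
}

#' @export
list_to_template <- function(x) {
  x$segments <- lapply(x$segments, function(s) {
    s$group <- s$group %||% NULL
    s
  })
  structure(x[c("name", "segments")], class = "rosetta_template")
}

#' Derive the display template of a schema
#'
#' When the schema declares display templates, the first (default) one is
#' returned. Otherwise the canonical derivation is used: the subject slot
#' (with its pre/post texts), the verb, then each object slot in index
#' order with its pre/post texts -- every role exactly once.
#'
#' @param schema a `rosetta_schema`
#' @return a `rosetta_template`
#' @export
derive_label_template <- function(schema) {
  if (length(schema$display_templates))
    return(schema$display_templates[[1]])
  segs <- list(seg_slot("subject", pre = schema$subject$pre,
                        post = schema$subject$post),
               seg_verb())
  for (p in schema$objects)
    segs[[length(segs) + 1L]] <- seg_slot(p$role, pre = p$pre, post = p$post)
  label_template(segs)
}

.join_values <- function(vals) {
  n <- length(vals)
  if (n == 1L) vals
  else if (n == 2L) paste(vals[1], "and", vals[2])
  else paste0(paste(vals[-n], collapse = ", "), ", and ", vals[n])
}

.render_binding <- function(b) {
  if (inherits(b, "rosetta_resource")) b$label %||% b$iri
  else b$display %||% b$lexical
}

.glue_tokens <- function(tokens) {
  out <- paste(tokens[nzchar(tokens)], collapse = " ")
  out <- gsub("( ", "(", out, fixed = TRUE)
  out <- gsub(" )", ")", out, fixed = TRUE)
  out <- gsub(" %", "%", out, fixed = TRUE)
  out <- gsub(" ,", ",", out, fixed = TRUE)
  out <- gsub(" :", ":", out, fixed = TRUE)
  out <- gsub("– ", "–", gsub(" –", "–", out))
  gsub("  +", " ", out)
}

#' Render a statement through a display template
#'
#' Slots are replaced by resource labels / literal display or lexical forms
#' verbatim; empty optional positions drop their pre/post texts (and their
#' whole group, if any); multi-valued positions join in order-rank order
#' with a serial comma ("A, B, and C"). Negated statements are prefixed
#' with "It is not the case that".
#'
#' @param template a `rosetta_template`
#' @param statement a `rosetta_statement` (or a `rosetta_version`)
#' @param schema the statement's schema
#' @return rendered sentence
#' @export
render_label <- function(template, statement, schema) {
  if (inherits(statement, "rosetta_version")) statement <- statement$statement
  values_of <- function(role) {
    if (role == "subject") statement$subject_bindings
    else statement$bindings[[role]] %||% list()
  }
  required_of <- function(role) {
    if (role == "subject") TRUE else schema_position(schema, role)$required
  }
  dead_groups <- character(0)
  for (s in template$segments)
    if (s$kind == "slot" && !is.null(s$group) && !length(values_of(s$role)))
      dead_groups <- c(dead_groups, s$group)
  tokens <- character(0)
  for (s in template$segments) {
    if (!is.null(s$group) && s$group %in% dead_groups) next
    if (s$kind == "text") tokens <- c(tokens, s$text)
    else if (s$kind == "verb") tokens <- c(tokens, schema$verb_text)
    else {
      vals <- values_of(s$role)
      if (!length(vals)) {
        if (required_of(s$role))
          stop("cannot render: required position ", s$role, " is empty")
        next
      }
      rendered <- .join_values(vapply(vals, .render_binding, character(1)))
      tokens <- c(tokens, s$pre, rendered, s$post)
    }
  }
  out <- .glue_tokens(tokens)
  if (statement$negated) paste0("It is not the case that ", out)
  else out
}

#' Template string with role placeholders
#'
#' Renders the template with each slot replaced by its role label (the
#' subject slot by the subject's role label), e.g.
#' "PERSON travels by TRANSPORTATION from DEPARTURE_LOCATION ...".
#' @param template a `rosetta_template`
#' @param schema the schema
#' @return template string
#' @export
template_to_string <- function(template, schema) {
  tokens <- character(0)
  for (s in template$segments) {
    if (s$kind == "text") tokens <- c(tokens, s$text)
    else if (s$kind == "verb") tokens <- c(tokens, schema$verb_text)
    else {
      role <- if (s$role == "subject") schema$subject$role else s$role
      tokens <- c(tokens, s$pre, role, s$post)
    }
  }
  .glue_tokens(tokens)
}

#' Render statements as a mind-map pattern
#'
#' One predicate node per statement (labelled with the verb), one node per
#' subject/object value, and labelled edges from the predicate node to each
#' bound position. Resource nodes are merged across statements by IRI;
#' literal nodes stay statement-local.
#'
#' @param statements list of `rosetta_statement`
#' @param registry a [schema_registry()] resolving their types
#' @return a `rosetta_mindmap` with `nodes` and `edges` data frames
#' @export
render_mindmap <- function(statements, registry) {
  nodes <- list(); edges <- list()
  add_node <- function(id, label, kind) {
    if (is.null(nodes[[id]])) nodes[[id]] <<- list(id = id, label = label,
                                                   kind = kind)
  }
  for (st in statements) {
    schema <- registry[[st$type_iri]]
    if (is.null(schema)) stop("unresolvable statement type: ", st$type_iri)
    pid <- st$statement_iri
    add_node(pid, schema$verb_text, "predicate")
    link <- function(b, role, k) {
      if (inherits(b, "rosetta_resource")) {
        add_node(b$iri, b$label %||% b$iri, "entity")
        to <- b$iri
      } else {
        to <- paste0(pid, "#", role, "#", k)
        add_node(to, .render_binding(b), "literal")
      }
      edges[[length(edges) + 1L]] <<- list(from = pid, to = to, label = role)
    }
    for (k in seq_along(st$subject_bindings))
      link(st$subject_bindings[[k]], schema$subject$role, k)
    for (role in names(st$bindings))
      for (k in seq_along(st$bindings[[role]]))
        link(st$bindings[[role]][[k]], role, k)
  }
  nodes_df <- do.call(rbind, lapply(unname(nodes), function(n)
    data.frame(id = n$id, label = n$label, kind = n$kind,
               stringsAsFactors = FALSE)))
  edges_df <- do.call(rbind, lapply(edges, function(e)
    data.frame(from = e$from, to = e$to, label = e$label,
               stringsAsFactors = FALSE)))
  structure(list(nodes = nodes_df %||% data.frame(id = character(),
                   label = character(), kind = character()),
                 edges = edges_df %||% data.frame(from = character(),
                   to = character(), label = character())),
            class = "rosetta_mindmap")
}

#' Export a mind-map as Graphviz DOT
#' @param mindmap a `rosetta_mindmap`
#' @return DOT text
#' @export
mindmap_to_dot <- function(mindmap) {
  q <- function(x) paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")
  n <- mindmap$nodes; e <- mindmap$edges
  lines <- c("digraph mindmap {",
             if (!is.null(n) && nrow(n)) sprintf("  %s [label=%s, shape=%s];",
               q(n$id), q(n$label),
               ifelse(n$kind == "predicate", "diamond",
                      ifelse(n$kind == "literal", "note", "ellipse"))),
             if (!is.null(e) && nrow(e)) sprintf("  %s -> %s [label=%s];",
               q(e$from), q(e$to), q(e$label)),
             "}")
  paste(lines, collapse = "\n")
}

#' Export a mind-map as a JSON node/edge list
#' @param mindmap a `rosetta_mindmap`
#' @return JSON text
#' @export
mindmap_to_json <- function(mindmap) {
  as.character(jsonlite::toJSON(list(nodes = mindmap$nodes,
                                     edges = mindmap$edges),
                                dataframe = "rows", pretty = TRUE))
}

#' @export
print.rosetta_template <- function(x, ...) {
  cat("<rosetta_template> '", x$name, "', ", length(x$segments),
      " segments\n", sep = "")
  invisible(x)
}

#' @export
print.rosetta_mindmap <- function(x, ...) {
  cat("<rosetta_mindmap> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}
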