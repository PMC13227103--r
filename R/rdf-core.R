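#' @title In-memory RDF quad store
#' @description
#' A minimal RDF graph container used throughout the package. Triples (or
#' quads, when `graph` is set) are held in a data frame with one row per
#' statement. IRIs are plain strings; literals carry an XSD datatype IRI.
#' The store never uses blank nodes: every node the package mints has a
#' stable IRI, so graphs can be diffed, sorted and compared textually.
#' @name rdf-core
NULL

.rdf_cols <- c("subject", "predicate", "object", "object_is_iri",
               "datatype", "graph")

#' Create an empty RDF graph
#'
#' @param prefixes named character vector of prefix -> namespace IRI
#'   mappings used when serializing to Turtle/TriG.
#' @return an object of class `rosetta_graph`
#' @export
rdf_graph <- function(prefixes = default_prefixes()) {
  df <- data.frame(subject = character(), predicate = character(),
                   object = character(), object_is_iri = logical(),
                   datatype = character(), graph = character(),
                   stringsAsFactors = FALSE)
  structure(df, prefixes = prefixes, class = c("rosetta_graph", "data.frame"))
}

#' Standard namespace prefixes
#' @return named character vector
#' @export
default_prefixes <- function() {
  c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd  = "http://www.w3.org/2001/XMLSchema#",
    sh   = "http://www.w3.org/ns/shacl#",
    np   = "http://www.nanopub.org/nschema#",
    rosetta = getOption("rosettastmt.base_iri", "https://w3id.org/rosetta/"))
}

RDF_TYPE   <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"

#' XSD datatype IRI from a short name
#' @param name e.g. "string", "float"
#' @return IRI string
#' @export
xsd_iri <- function(name) paste0("http://www.w3.org/2001/XMLSchema#", name)

#' Build triple rows
#'
#' Vectorized constructor for triple rows; all literal-description columns
#' are recycled.
#' @param s,p subject and predicate IRIs
#' @param o object IRI or literal lexical form
#' @param is_iri logical, whether `o` is an IRI
#' @param datatype datatype IRI for literals (`NA` for IRIs and plain strings)
#' @param graph named-graph IRI or `NA` for the default graph
#' @return data frame of triple rows
#' @export
triple <- function(s, p, o, is_iri = TRUE, datatype = NA_character_,
                   graph = NA_character_) {
  data.frame(subject = as.character(s), predicate = as.character(p),
             object = as.character(o), object_is_iri = is_iri,
             datatype = as.character(datatype), graph = as.character(graph),
             stringsAsFactors = FALSE)
}

#' Literal triple helper
#' @inheritParams triple
#' @param datatype datatype IRI; defaults to xsd:string
#' @export
lit_triple <- function(s, p, o, datatype = xsd_iri("string"),
                       graph = NA_character_) {
  triple(s, p, o, is_iri = FALSE, datatype = datatype, graph = graph)
}

#' Add rows to a graph
#' @param graph a `rosetta_graph`
#' @param ... data frames of triple rows (from [triple()] / [lit_triple()])
#' @return the extended graph
#' @export
g_add <- function(graph, ...) {
  rows <- do.call(rbind, list(...))
  out <- rbind(as.data.frame(graph), rows[, .rdf_cols])
  structure(out, prefixes = attr(graph, "prefixes"),
            class = c("rosetta_graph", "data.frame"))
}

#' Merge graphs
#' @param ... `rosetta_graph` objects
#' @return merged graph carrying the first graph's prefixes
#' @export
g_union <- function(...) {
  gs <- list(...)
  out <- do.call(rbind, lapply(gs, as.data.frame))
  structure(out, prefixes = attr(gs[[1]], "prefixes"),
            class = c("rosetta_graph", "data.frame"))
}

#' Match triples
#'
#' @param graph a `rosetta_graph`
#' @param s,p,o optional filters (exact match); `o` matches the object
#'   column regardless of kind
#' @param g optional named-graph filter
#' @return data frame of matching rows
#' @export
g_match <- function(graph, s = NULL, p = NULL, o = NULL, g = NULL) {
  df <- as.data.frame(graph)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$subject %in% s
  if (!is.null(p)) keep <- keep & df$predicate %in% p
  if (!is.null(o)) keep <- keep & df$object %in% o
  if (!is.null(g)) keep <- keep & !is.na(df$graph) & df$graph %in% g
  df[keep, , drop = FALSE]
}

#' Objects of matching triples
#' @inheritParams g_match
#' @return character vector of object terms
#' @export
g_objects <- function(graph, s = NULL, p = NULL) g_match(graph, s = s, p = p)$object

#' Canonicalize a graph
#'
#' Deduplicates and sorts rows into a deterministic order so that identical
#' graphs always serialize to identical text.
#' @param graph a `rosetta_graph`
#' @return canonical graph
#' @export
g_canonical <- function(graph) {
  df <- unique(as.data.frame(graph))
  key_g <- ifelse(is.na(df$graph), "", df$graph)
  key_dt <- ifelse(is.na(df$datatype), "", df$datatype)
  ord <- order(key_g, df$subject, df$predicate, !df$object_is_iri,
               df$object, key_dt, method = "radix")
  structure(df[ord, , drop = FALSE], prefixes = attr(graph, "prefixes"),
            class = c("rosetta_graph", "data.frame"))
}

#' Graph equality (set semantics)
#' @param a,b graphs
#' @return logical
#' @export
g_equal <- function(a, b) {
  ca <- g_canonical(a); cb <- g_canonical(b)
  rownames(ca) <- NULL; rownames(cb) <- NULL
  isTRUE(all.equal(as.data.frame(ca), as.data.frame(cb),
                   check.attributes = FALSE))
}

#' Subgraph test
#' @param small,big graphs
#' @return TRUE if every quad of `small` occurs in `big`
#' @export
g_contains <- function(big, small) {
  key <- function(df) paste(df$subject, df$predicate, df$object,
                            df$object_is_iri,
                            ifelse(is.na(df$datatype), "", df$datatype),
                            ifelse(is.na(df$graph), "", df$graph), sep = "\r")
  all(key(as.data.frame(small)) %in% key(as.data.frame(big)))
}

#' @export
print.rosetta_graph <- function(x, ...) {
  cat("<rosetta_graph> ", nrow(x), " triples",
      if (any(!is.na(x$graph))) paste0(" in ", length(unique(stats::na.omit(x$graph))),
                                       " named graph(s)"), "\n", sep = "")
  invisible(x)
}

## ---- term formatting ------------------------------------------------------

.pn_local_ok <- function(x) grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", x)

format_iri <- function(iri, prefixes) {
  for (i in seq_along(prefixes)) {
    ns <- prefixes[[i]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (nzchar(local) && .pn_local_ok(local))
        return(paste0(names(prefixes)[i], ":", local))
    }
  }
  paste0("<", iri, ">")
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    res <- character(0); j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else { res <- c(res, ch); j <- j + 1L }
    }
    out[i] <- paste0(res, collapse = "")
  }
  out
}

format_object <- function(o, is_iri, datatype, prefixes) {
  if (is_iri) return(format_iri(o, prefixes))
  lex <- paste0("\"", escape_literal(o), "\"")
  if (is.na(datatype) || datatype == xsd_iri("string")) return(lex)
  paste0(lex, "^^", format_iri(datatype, prefixes))
}

format_triple_line <- function(row, prefixes) {
  paste0(format_iri(row$subject, prefixes), " ",
         if (row$predicate == RDF_TYPE) "a" else format_iri(row$predicate, prefixes),
         " ", format_object(row$object, row$object_is_iri, row$datatype, prefixes),
         " .")
}

used_prefixes <- function(df, prefixes) {
  text <- c(df$subject, df$predicate, df$object[df$object_is_iri],
            stats::na.omit(df$datatype))
  keep <- vapply(prefixes, function(ns) any(startsWith(text, ns)), logical(1))
  prefixes[keep]
}

## ---- writers --------------------------------------------------------------

#' Serialize a graph as canonical Turtle
#'
#' One sorted triple per line; deterministic, so equal graphs give byte-equal
#' output. Named-graph rows are not allowed (use [write_trig()]).
#' @param graph a `rosetta_graph`
#' @param file optional path; when given, text is written there
#' @return the Turtle text, invisibly when `file` is given
#' @export
write_turtle <- function(graph, file = NULL) {
  df <- as.data.frame(g_canonical(graph))
  if (any(!is.na(df$graph)))
    stop("graph contains named-graph quads; use write_trig()")
  px <- used_prefixes(df, attr(graph, "prefixes"))
  header <- sprintf("@prefix %s: <%s> .", names(px), unname(px))
  lines <- vapply(seq_len(nrow(df)), function(i)
    format_triple_line(df[i, ], px), character(1))
  txt <- paste0(paste(c(header, "", lines), collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

#' Serialize a graph as canonical TriG
#' @inheritParams write_turtle
#' @export
write_trig <- function(graph, file = NULL) {
  df <- as.data.frame(g_canonical(graph))
  px <- used_prefixes(df, attr(graph, "prefixes"))
  header <- sprintf("@prefix %s: <%s> .", names(px), unname(px))
  out <- header
  dflt <- df[is.na(df$graph), , drop = FALSE]
  if (nrow(dflt)) {
    out <- c(out, "", vapply(seq_len(nrow(dflt)), function(i)
      format_triple_line(dflt[i, ], px), character(1)))
  }
  for (gname in unique(df$graph[!is.na(df$graph)])) {
    block <- df[!is.na(df$graph) & df$graph == gname, , drop = FALSE]
    out <- c(out, "", paste0(format_iri(gname, px), " {"),
             paste0("    ", vapply(seq_len(nrow(block)), function(i)
               format_triple_line(block[i, ], px), character(1))),
             "}")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

#' Serialize a graph as N-Quads
#' @inheritParams write_turtle
#' @export
write_nquads <- function(graph, file = NULL) {
  df <- as.data.frame(g_canonical(graph))
  obj <- ifelse(df$object_is_iri, paste0("<", df$object, ">"),
                ifelse(is.na(df$datatype) | df$datatype == xsd_iri("string"),
                       paste0("\"", escape_literal(df$object), "\""),
                       paste0("\"", escape_literal(df$object), "\"^^<",
                              df$datatype, ">")))
  lines <- paste0("<", df$subject, "> <", df$predicate, "> ", obj,
                  ifelse(is.na(df$graph), "", paste0(" <", df$graph, ">")), " .")
  txt <- if (nrow(df)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

#' Serialize a graph as expanded JSON-LD
#'
#' Emits the expanded JSON-LD form: an array of node objects with `@id`,
#' `@type` and predicate arrays of `{"@id"}` / `{"@value", "@type"}` entries.
#' Named-graph rows are grouped under `@graph` containers.
#' @inheritParams write_turtle
#' @export
write_jsonld <- function(graph, file = NULL) {
  df <- as.data.frame(g_canonical(graph))
  node_objects <- function(block) {
    out <- list()
    for (s in unique(block$subject)) {
      rows <- block[block$subject == s, , drop = FALSE]
      node <- list(`@id` = s)
      types <- rows$object[rows$predicate == RDF_TYPE & rows$object_is_iri]
      if (length(types)) node$`@type` <- as.list(types)
      rest <- rows[rows$predicate != RDF_TYPE, , drop = FALSE]
      for (p in unique(rest$predicate)) {
        pr <- rest[rest$predicate == p, , drop = FALSE]
        vals <- lapply(seq_len(nrow(pr)), function(i) {
          if (pr$object_is_iri[i]) list(`@id` = pr$object[i])
          else if (is.na(pr$datatype[i]) || pr$datatype[i] == xsd_iri("string"))
            list(`@value` = pr$object[i])
          else list(`@value` = pr$object[i], `@type` = pr$datatype[i])
        })
        node[[p]] <- vals
      }
      out[[length(out) + 1L]] <- node
    }
    out
  }
  top <- node_objects(df[is.na(df$graph), , drop = FALSE])
  for (gname in unique(df$graph[!is.na(df$graph)])) {
    block <- df[!is.na(df$graph) & df$graph == gname, , drop = FALSE]
    top[[length(top) + 1L]] <- list(`@id` = gname, `@graph` = node_objects(block))
  }
  txt <- jsonlite::toJSON(top, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  as.character(txt)
}

## ---- parsers --------------------------------------------------------------

.tokenize_rdf_line <- function(line) {
  pat <- paste0(
    "<[^>]*>",
    "|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^(?:<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+))?",
    "|@prefix",
    "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*",
    "|\\ba\\b|\\.|\\{|\\}")
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]
}

.resolve_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
  if (tok == "a") return(RDF_TYPE)
  parts <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_.-]*):(.*)$", tok))[[1]]
  ns <- prefixes[[parts[2]]]
  if (is.null(ns)) stop("unknown prefix in term: ", tok)
  paste0(ns, parts[3])
}

.parse_object_tok <- function(tok, prefixes) {
  if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec(
      "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^(.+))?$", tok, perl = TRUE))[[1]]
    lex <- unescape_literal(m[2])
    dt <- if (is.na(m[3]) || !nzchar(m[3])) xsd_iri("string")
          else .resolve_term(m[3], prefixes)
    list(o = lex, is_iri = FALSE, dt = dt)
  } else {
    list(o = .resolve_term(tok, prefixes), is_iri = TRUE, dt = NA_character_)
  }
}

#' Parse Turtle or TriG text written by this package
#'
#' Supports the canonical subset emitted by [write_turtle()] and
#' [write_trig()]: `@prefix` directives, one triple per line, full IRIs,
#' prefixed names, `a`, typed literals, and `<graph> { ... }` blocks.
#' Blank nodes are deliberately unsupported (the package never emits them).
#' @param text Turtle/TriG text (single string or character vector of lines)
#' @return a `rosetta_graph`
#' @export
parse_turtle <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  prefixes <- c()
  rows <- list()
  current_graph <- NA_character_
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- .tokenize_rdf_line(line)
    if (!length(toks)) next
    if (toks[1] == "@prefix") {
      pn <- sub(":.*$", "", toks[2])
      iri <- substr(toks[3], 2L, nchar(toks[3]) - 1L)
      prefixes[pn] <- iri
      next
    }
    if (length(toks) >= 2 && toks[2] == "{") {
      current_graph <- .resolve_term(toks[1], prefixes)
      toks <- toks[-(1:2)]
      if (!length(toks)) next
    }
    if (toks[length(toks)] == "}") {
      toks <- toks[-length(toks)]
      close_after <- TRUE
    } else close_after <- FALSE
    if (length(toks) && toks[length(toks)] == ".") toks <- toks[-length(toks)]
    if (length(toks) == 1 && toks[1] == "}") { current_graph <- NA_character_; next }
    if (length(toks)) {
      if (length(toks) != 3) stop("cannot parse line: ", line)
      s <- .resolve_term(toks[1], prefixes)
      p <- .resolve_term(toks[2], prefixes)
      ob <- .parse_object_tok(toks[3], prefixes)
      rows[[length(rows) + 1L]] <- triple(s, p, ob$o, ob$is_iri, ob$dt,
                                          graph = current_graph)
    }
    if (close_after) current_graph <- NA_character_
  }
  g <- rdf_graph(prefixes = if (length(prefixes)) prefixes else default_prefixes())
  if (length(rows)) g <- g_add(g, do.call(rbind, rows))
  g
}

#' Parse N-Quads / N-Triples text
#' @param text N-Quads text
#' @return a `rosetta_graph`
#' @export
parse_nquads <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rows <- list()
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>)?)",
                "(?:\\s+<([^>]*)>)?\\s*\\.\\s*$")
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec(pat, line, perl = TRUE))[[1]]
    if (!length(m)) stop("cannot parse N-Quads line: ", line)
    obj_tok <- m[4]
    if (startsWith(obj_tok, "<")) {
      ob <- list(o = substr(obj_tok, 2, nchar(obj_tok) - 1),
                 is_iri = TRUE, dt = NA_character_)
    } else {
      mm <- regmatches(obj_tok, regexec(
        "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>)?$", obj_tok,
        perl = TRUE))[[1]]
      dt <- if (is.na(mm[3]) || !nzchar(mm[3])) xsd_iri("string") else mm[3]
      ob <- list(o = unescape_literal(mm[2]), is_iri = FALSE, dt = dt)
    }
    gname <- if (length(m) >= 5 && !is.na(m[5]) && nzchar(m[5])) m[5] else NA_character_
    rows[[length(rows) + 1L]] <- triple(m[2], m[3], ob$o, ob$is_iri, ob$dt,
                                        graph = gname)
  }
  g <- rdf_graph()
  if (length(rows)) g <- g_add(g, do.call(rbind, rows))
  g
}

#' Parse expanded JSON-LD written by this package
#' @param text JSON-LD text
#' @return a `rosetta_graph`
#' @export
parse_jsonld <- function(text) {
  nodes <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  rows <- list()
  emit_node <- function(node, gname) {
    s <- node$`@id`
    for (ty in node$`@type`)
      rows[[length(rows) + 1L]] <<- triple(s, RDF_TYPE, ty, TRUE, graph = gname)
    for (p in setdiff(names(node), c("@id", "@type", "@graph"))) {
      for (v in node[[p]]) {
        if (!is.null(v$`@id`)) {
          rows[[length(rows) + 1L]] <<- triple(s, p, v$`@id`, TRUE, graph = gname)
        } else {
          dt <- if (is.null(v$`@type`)) xsd_iri("string") else v$`@type`
          rows[[length(rows) + 1L]] <<- triple(s, p, as.character(v$`@value`),
                                               FALSE, dt, graph = gname)
        }
      }
    }
    for (sub in node$`@graph`) emit_node(sub, node$`@id`)
  }
  for (node in nodes) emit_node(node, NA_character_)
  g <- rdf_graph()
  if (length(rows)) g <- g_add(g, do.call(rbind, rows))
  g
}
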