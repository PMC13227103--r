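#' The rosetta term vocabulary
#'
#' All properties and classes of the statement metamodel live in a single
#' configurable namespace. The canonical namespace of the published ontology
#' is not fixed here; the default is provisional and can be changed globally
#' via `options(rosettastmt.base_iri = ...)` or per call.
#'
#' @param base namespace IRI prefix for all rosetta terms
#' @return a list of term IRIs (class `rosetta_vocabulary`)
#' @export
rosetta_vocabulary <- function(base = getOption("rosettastmt.base_iri",
                                                "https://w3id.org/rosetta/")) {
  term <- function(x) paste0(base, x)
  structure(list(
    ns                = base,
    statement_class   = term("Statement"),
    negation_class    = term("Negation"),
    subject_position_class = term("SubjectPosition"),
    subject           = term("subject"),
    has_version       = term("hasVersion"),
    has_data_schema   = term("hasDataSchema"),
    has_context       = term("hasContext"),
    has_statement     = term("hasStatement"),
    has_object_position = term("hasObjectPosition"),
    required_object_position = term("requiredObjectPosition"),
    optional_object_position = term("optionalObjectPosition"),
    order             = term("order"),
    value             = term("value"),
    display_text      = term("displayText"),
    deleted_at        = term("deletedAt"),
    deleted_by        = term("deletedBy"),
    certainty         = term("certainty"),
    version_number    = term("versionNumber"),
    version_identifier = term("versionIdentifier"),
    creator           = term("creator"),
    created_at        = term("createdAt"),
    author            = term("author"),
    extraction_method = term("extractionMethod"),
    imported_from     = term("importedFrom"),
    modifiable        = term("modifiable")
  ), class = "rosetta_vocabulary")
}

#' Numbered position property of the light dialect
#'
#' The light metamodel links a statement instance to each of its objects via
#' a sequentially numbered property drawn from four families:
#' required/optional crossed with resource/literal. A single index sequence
#' is shared across the families (the position's schema index).
#'
#' @param vocab a [rosetta_vocabulary()]
#' @param required logical: argument (TRUE) or adjunct (FALSE)
#' @param literal logical: literal-object or resource-object family
#' @param index 1-based position index
#' @return property IRI
#' @export
position_property <- function(vocab, required, literal, index) {
  paste0(vocab$ns, if (required) "required" else "optional",
         if (literal) "LiteralObjectPosition" else "ObjectPosition", index)
}

#' Companion display-text property for a numbered light-dialect position
#' @inheritParams position_property
#' @return property IRI
#' @export
position_display_property <- function(vocab, required, literal, index) {
  paste0(position_property(vocab, required, literal, index), "Display")
}

.position_prop_regex <- function(vocab) {
  paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", vocab$ns),
         "(required|optional)(Literal)?ObjectPosition([0-9]+)$")
}

#' Decompose a numbered position property
#' @param vocab a [rosetta_vocabulary()]
#' @param iri property IRI
#' @return `NULL` if not a member of the families, else a list with
#'   `required`, `literal`, `index`
#' @export
parse_position_property <- function(vocab, iri) {
  m <- regmatches(iri, regexec(.position_prop_regex(vocab), iri))[[1]]
  if (!length(m)) return(NULL)
  list(required = m[2] == "required", literal = nzchar(m[3]),
       index = as.integer(m[4]))
}

#' Self-describing ontology graph for the vocabulary
#'
#' Emits every vocabulary term with its RDF type and a label, including the
#' numbered light-dialect property families up to `max_positions`.
#' @param vocab a [rosetta_vocabulary()]
#' @param max_positions number of numbered properties per family to emit
#' @return a `rosetta_graph`
#' @export
vocabulary_graph <- function(vocab = rosetta_vocabulary(), max_positions = 10L) {
  g <- rdf_graph(prefixes = c(default_prefixes(), rosetta = vocab$ns))
  rdfs_class <- "http://www.w3.org/2000/01/rdf-schema#Class"
  rdf_prop <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property"
  classes <- c(vocab$statement_class, vocab$negation_class,
               vocab$subject_position_class)
  props <- setdiff(unlist(vocab[!(names(vocab) %in%
             c("ns", "statement_class", "negation_class",
               "subject_position_class"))]), NA)
  for (i in seq_len(max_positions))
    for (req in c(TRUE, FALSE)) for (lit in c(TRUE, FALSE))
      props <- c(props, position_property(vocab, req, lit, i))
  label_of <- function(iri) {
    loc <- sub(paste0("^", vocab$ns), "", iri)
    tolower(gsub("([a-z])([A-Z0-9])", "\\1 \\2", loc))
  }
  for (cl in classes)
    g <- g_add(g, triple(cl, RDF_TYPE, rdfs_class),
               lit_triple(cl, RDFS_LABEL, label_of(cl)))
  for (p in props)
    g <- g_add(g, triple(p, RDF_TYPE, rdf_prop),
               lit_triple(p, RDFS_LABEL, label_of(p)))
  g
}
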