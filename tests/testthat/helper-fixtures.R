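# Shared fixtures built in code: the packaged schemata and worked examples,
# plus small random-schema / random-statement generators for property tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

fx_schemas <- function() rosetta_fixture_schemas()

fx_statements <- function(seed = 1) {
  set.seed(seed)
  rosetta_paper_statements(fx_schemas())
}

fx_registry <- function() schema_registry(unname(fx_schemas()))

wd <- function(q) paste0("http://www.wikidata.org/entity/", q)

# A randomized well-formed statement type: mixed resource/literal positions,
# random required flags and cardinalities.
rand_schema <- function(n_pos = sample(0:6, 1)) {
  dts <- c("integer", "decimal", "float", "date", "text", "boolean")
  mk_pos <- function(i) {
    if (runif(1) < 0.5)
      position_spec(paste0("ROLE_", i),
                    constraint_spec("resource",
                                    value_class = paste0("https://example.org/class/c", i)),
                    required = runif(1) < 0.6,
                    max_values = sample(c(1, 2, 3, Inf), 1))
    else
      position_spec(paste0("ROLE_", i),
                    constraint_spec("literal", datatype = sample(dts, 1)),
                    required = runif(1) < 0.6,
                    max_values = sample(c(1, 2, Inf), 1))
  }
  define_statement_type(
    label = paste0("predicate ", paste(sample(letters, 6), collapse = "")),
    subject_spec = position_spec("SUBJ",
      constraint_spec("resource", value_class = "https://example.org/class/subject")),
    object_specs = lapply(seq_len(n_pos), mk_pos))
}

rand_lexical <- function(datatype_iri) {
  switch(sub("^.*#", "", datatype_iri),
    integer = as.character(sample.int(1000, 1)),
    decimal = format(round(runif(1, 0, 100), 3), nsmall = 3),
    float   = format(round(runif(1, 0, 100), 2), nsmall = 2),
    date    = format(as.Date("2020-01-01") + sample.int(1000, 1)),
    boolean = sample(c("true", "false"), 1),
    paste(sample(letters, 8), collapse = ""))
}

# A random statement valid against `schema`: all required positions bound,
# optional ones with probability 0.5, multi-valued sometimes.
rand_statement_for <- function(schema) {
  mk_val <- function(p, k) {
    if (p$constraint$kind == "resource")
      resource_ref(paste0("https://example.org/entity/", iri_slug(p$role),
                          "-", sample.int(1e6, 1)),
                   label = paste0(tolower(p$role), " ", k),
                   class_iri = p$constraint$value_class)
    else typed_literal(rand_lexical(p$constraint$datatype_iri),
                       p$constraint$datatype_iri)
  }
  bindings <- list()
  for (p in schema$objects) {
    if (!p$required && runif(1) > 0.5) next
    n <- min(sample.int(3, 1), p$max_values)
    vals <- lapply(seq_len(n), function(k) mk_val(p, k))
    keys <- vapply(vals, function(b)
      if (inherits(b, "rosetta_resource")) b$iri
      else paste0(b$lexical, b$datatype_iri), character(1))
    bindings[[p$role]] <- vals[!duplicated(keys)]
  }
  create_statement(schema,
                   resource_ref(paste0("https://example.org/entity/subj-",
                                       sample.int(1e6, 1)),
                                label = "subject entity"),
                   bindings,
                   metadata = provenance_metadata(creator = "tester",
                     created_at = "2024-01-01T00:00:00Z"),
                   negated = runif(1) < 0.1,
                   certainty = if (runif(1) < 0.3) round(runif(1), 2))
}

python_bin <- function() Sys.which("python")

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2(python_bin(), f, stdout = TRUE, stderr = TRUE))
  attr(out, "status") <- attr(out, "status") %||% 0L
  out
}
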