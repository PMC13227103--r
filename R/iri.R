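#' IRI minting
#'
#' Instance IRIs are UUIDv4-based and drawn from R's RNG, so minting is
#' reproducible under a fixed seed. Type-level IRIs are slugged from display
#' labels. No blank nodes are ever used: stable node identity is what makes
#' version diffs and round-trip comparisons deterministic.
#' @name iri
NULL

#' Slug a label for use in an IRI
#' @param label display label
#' @return lowercase hyphenated slug
#' @export
iri_slug <- function(label) {
  s <- tolower(trimws(label))
  s <- gsub("[^a-z0-9]+", "-", s)
  gsub("^-|-$", "", s)
}

.uuid4 <- function() {
  h <- sample(c(0:9, letters[1:6]), 32L, replace = TRUE)
  h[13] <- "4"
  h[17] <- sample(c("8", "9", "a", "b"), 1L)
  paste0(paste(h[1:8], collapse = ""), "-", paste(h[9:12], collapse = ""), "-",
         paste(h[13:16], collapse = ""), "-", paste(h[17:20], collapse = ""),
         "-", paste(h[21:32], collapse = ""))
}

#' Mint a fresh instance IRI
#'
#' @param kind path segment naming the kind of resource
#'   (e.g. "statement", "anchor")
#' @param base namespace base IRI
#' @return an absolute IRI; 122 random bits make collisions negligible, and
#'   minting is reproducible under `set.seed()`
#' @export
mint_iri <- function(kind, base = getOption("rosettastmt.base_iri",
                                            "https://w3id.org/rosetta/")) {
  paste0(base, "resource/", kind, "/", .uuid4())
}
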