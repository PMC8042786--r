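#' Lexical databases for term expansion
#'
#' A lexical database maps a term to ranked lists of related terms under the
#' four relations used for lexicon expansion: `synonym`, `hypernym`,
#' `hyponym` and `antonym` (the relations a WordNet-style resource exposes).
#' The package treats the database as a pluggable interface: any object with
#' class `phq_lexdb` wrapping `term -> relation -> character vector` works.
#'
#' `lexdb()` builds one from a named list; `read_lexdb_json()` loads the JSON
#' fixture format `{"term": {"relation": ["t1", "t2", ...]}}`.
#'
#' @param entries Named list. Names are terms; each element is a named list of
#'   character vectors keyed by relation.
#' @return An object of class `phq_lexdb`.
#' @examples
#' db <- lexdb(list(sleep = list(synonym = c("slumber", "nap"))))
#' lexdb_lookup(db, "sleep", "synonym")
#' @export
lexdb <- function(entries = list()) {
  stopifnot(is.list(entries))
  if (length(entries) > 0 && is.null(names(entries))) {
    abort("lexdb entries must be a named list (term -> relation -> terms).")
  }
  entries <- lapply(entries, function(rels) {
    lapply(rels, function(x) tolower(as.character(x)))
  })
  names(entries) <- tolower(names(entries))
  structure(list(entries = entries), class = "phq_lexdb")
}

LEXDB_RELATIONS <- c("synonym", "hypernym", "hyponym", "antonym")

#' Look up related terms
#'
#' @param db A `phq_lexdb`.
#' @param term Character scalar; lookup is case-insensitive.
#' @param relation One of `"synonym"`, `"hypernym"`, `"hyponym"`,
#'   `"antonym"`.
#' @return Character vector of related terms in database rank order; empty
#'   for unknown terms or relations the term lacks.
#' @export
lexdb_lookup <- function(db, term, relation) {
  stopifnot(inherits(db, "phq_lexdb"))
  relation <- match.arg(relation, LEXDB_RELATIONS)
  hit <- db$entries[[tolower(term)]]
  if (is.null(hit)) return(character(0))
  out <- hit[[relation]]
  if (is.null(out)) character(0) else out
}

#' @rdname lexdb
#' @param path Path to a JSON file of entries.
#' @export
read_lexdb_json <- function(path) {
  if (!file.exists(path)) abort(paste0("lexical database file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lexdb(raw)
}

#' @rdname lexdb
#' @param x A `phq_lexdb` to serialise.
#' @export
write_lexdb_json <- function(x, path) {
  stopifnot(inherits(x, "phq_lexdb"))
  jsonlite::write_json(x$entries, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @export
print.phq_lexdb <- function(x, ...) {
  cat("<phq_lexdb> ", length(x$entries), " terms\n", sep = "")
  invisible(x)
}
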