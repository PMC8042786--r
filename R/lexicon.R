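#' Load the PHQ-9 seed lexicon
#'
#' Reads the tab-separated seed lexicon: one row per symptom with columns
#' `id`, `phq9_text` (the questionnaire item) and a comma-separated list of
#' seed terms. The package bundles the nine-item PHQ-9 seed list (e.g. S9,
#' thoughts of self-harm: *dead, hurt, suicide*) as its default.
#'
#' @param path Path to a lexicon TSV. `NULL` (default) loads the bundled
#'   PHQ-9 seed list.
#' @return A tibble with columns `symptom_id`, `phq9_text` and `seeds`
#'   (list-column of lowercase character vectors), one row per symptom
#'   S1..S9.
#' @examples
#' seeds <- read_seed_lexicon()
#' seeds$seeds[[9]]
#' @export
read_seed_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "phq9_seed_lexicon.tsv",
                                package = "phqminer", mustWork = TRUE)
  if (!file.exists(path)) abort(paste0("seed lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad) > 0) {
    abort(paste0("malformed lexicon: row ", bad[1],
                 " does not have 3 tab-separated columns."))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("malformed lexicon: duplicated symptom id '",
                 ids[duplicated(ids)][1], "'."))
  }
  missing <- setdiff(SYMPTOM_IDS, ids)
  extra <- setdiff(ids, SYMPTOM_IDS)
  if (length(missing) > 0) {
    abort(paste0("malformed lexicon: missing symptom row(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  if (length(extra) > 0) {
    abort(paste0("malformed lexicon: unexpected row id '", extra[1], "'."))
  }
  seeds <- lapply(fields, function(f) {
    s <- tolower(trimws(strsplit(f[[3]], ",", fixed = TRUE)[[1]]))
    s <- s[nzchar(s)]
    if (length(s) == 0) abort(paste0("malformed lexicon: row ", f[[1]], " has no seed terms."))
    if (any(grepl("\\s", s))) {
      abort(paste0("malformed lexicon: row ", f[[1]],
                   " contains a seed with internal whitespace."))
    }
    unique(s)
  })
  out <- tibble::tibble(
    symptom_id = ids,
    phq9_text = vapply(fields, `[[`, "", 2L),
    seeds = seeds
  )
  out[match(SYMPTOM_IDS, out$symptom_id), ]
}

#' Expand symptom seed lexicons through a lexical database
#'
#' For every seed term of every symptom, looks up the requested relations in
#' the lexical database and appends up to `top_k` related terms per
#' (seed, relation) pair, in database rank order. Terms already present in
#' the symptom's lexicon are skipped, so seeds are never duplicated and the
#' result is monotone in `top_k`. Provenance (`seed`, `synonym`, `hypernym`,
#' `hyponym`, `antonym`) is recorded per term.
#'
#' @param seeds Seed lexicon tibble from [read_seed_lexicon()].
#' @param db A [lexdb()] lexical database (an empty one yields a seeds-only
#'   lexicon).
#' @param top_k Maximum related terms kept per seed and relation
#'   (non-negative; default 5, the expansion depth found to correlate with
#'   the original symptom terms).
#' @param relations Relations to expand; defaults to all four.
#' @return A `phq_lexicon`: a tibble with columns `symptom_id`, `term`,
#'   `provenance`, seeds first within each symptom.
#' @examples
#' db <- lexdb(list(sleep = list(synonym = c("slumber", "nap", "rest"))))
#' lex <- expand_lexicon(read_seed_lexicon(), db, top_k = 2)
#' dplyr::filter(lex, symptom_id == "S3")
#' @export
expand_lexicon <- function(seeds, db = lexdb(), top_k = 5,
                           relations = LEXDB_RELATIONS) {
  stopifnot(is.data.frame(seeds), inherits(db, "phq_lexdb"))
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 0) {
    abort("top_k must be a single non-negative number.")
  }
  relations <- match.arg(relations, LEXDB_RELATIONS, several.ok = TRUE)
  rows <- purrr::map2(seeds$symptom_id, seeds$seeds, function(sid, sd) {
    terms <- sd
    prov <- rep("seed", length(sd))
    for (seed in sd) {
      for (rel in relations) {
        cand <- lexdb_lookup(db, seed, rel)
        cand <- head(cand[!cand %in% terms & nzchar(cand)], top_k)
        # head() before the duplicate filter would change monotonicity in
        # top_k; filtering first keeps terms(top_k) a prefix of terms(top_k+1)
        # per (seed, relation) pass.
        if (length(cand) > 0) {
          terms <- c(terms, cand)
          prov <- c(prov, rep(rel, length(cand)))
        }
      }
    }
    keep <- !duplicated(terms)
    tibble::tibble(symptom_id = sid, term = terms[keep], provenance = prov[keep])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phq_lexicon", class(out))
  out
}

#' Turn one symptom's lexicon into a pseudo-document
#'
#' The weak labeler embeds each symptom lexicon as if it were a small
#' document. This returns the symptom's terms as a deterministic token
#' sequence: seed terms first (in questionnaire order), then expansions in
#' the order they were added, each term exactly once. Antonyms point away
#' from the symptom and are excluded unless requested.
#'
#' @param lexicon A `phq_lexicon` from [expand_lexicon()].
#' @param symptom_id One of `"S1"`..`"S9"`.
#' @param include_antonyms Keep antonym-provenance terms? Default `FALSE`.
#' @return Character vector of tokens.
#' @export
lexicon_document <- function(lexicon, symptom_id, include_antonyms = FALSE) {
  stopifnot(is.data.frame(lexicon))
  symptom_id <- match.arg(symptom_id, SYMPTOM_IDS)
  rows <- lexicon[lexicon$symptom_id == symptom_id, , drop = FALSE]
  if (!include_antonyms) rows <- rows[rows$provenance != "antonym", , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("empty lexicon for symptom ", symptom_id, "."))
  }
  ord <- order(rows$provenance != "seed")  # stable: seeds first, then insertion order
  unique(rows$term[ord])
}

#' Read and write expanded lexicons
#'
#' The on-disk format is TSV with columns `symptom_id`, `term`,
#' `provenance`; loading preserves row order, so a write/read round trip is
#' term-identical.
#'
#' @param lexicon A `phq_lexicon`.
#' @param path File path.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   returns a `phq_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(is.data.frame(lexicon))
  utils::write.table(as.data.frame(lexicon)[, c("symptom_id", "term", "provenance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("symptom_id", "term", "provenance")
  if (!all(need %in% names(df))) {
    abort("lexicon file must have columns symptom_id, term, provenance.")
  }
  out <- tibble::as_tibble(df[, need])
  class(out) <- c("phq_lexicon", class(out))
  out
}

#' Seeds-only lexicon
#'
#' Convenience wrapper: the seed lexicon reshaped to the long `phq_lexicon`
#' form without any expansion (equivalent to expanding through an empty
#' database).
#'
#' @inheritParams expand_lexicon
#' @return A `phq_lexicon` with all provenance `"seed"`.
#' @export
seeds_only_lexicon <- function(seeds = read_seed_lexicon()) {
  expand_lexicon(seeds, lexdb(), top_k = 0)
}
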