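#' Normalize patient-authored text
#'
#' Applies the pipeline's text cleaning, in order: validate UTF-8, lowercase,
#' expand contractions ("can't" becomes "cannot", from a shipped table),
#' drop URLs (tokens starting `http`/`https`), replace the meaningless
#' special characters `#`, `+`, `-`, `*`, `=` with a space (a space, not
#' deletion, so hyphenated compounds split rather than fuse), and collapse
#' runs of whitespace. The function is idempotent.
#'
#' @param text Character vector of raw post text.
#' @param contractions Two-column data frame (`contraction`, `expansion`);
#'   `NULL` loads the bundled table.
#' @return Character vector of normalized text.
#' @examples
#' normalize_text("Can't  STOP")
#' normalize_text("see https://x.y #sad")
#' @export
normalize_text <- function(text, contractions = NULL) {
  stopifnot(is.character(text))
  bad <- which(!validUTF8(text))
  if (length(bad) > 0) {
    abort(paste0("text element ", bad[1], " is not valid UTF-8 (byte offset ",
                 utf8_error_offset(text[bad[1]]), ")."))
  }
  contractions <- contractions %||% read_contractions()
  out <- tolower(text)
  for (i in seq_len(nrow(contractions))) {
    out <- gsub(paste0("\\b", contractions$contraction[i], "\\b"),
                contractions$expansion[i], out, perl = TRUE)
  }
  out <- gsub("\\bhttps?\\S*", " ", out, perl = TRUE)
  out <- gsub("[#+*=-]", " ", out)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

# First invalid byte offset (1-based) in a non-UTF-8 string.
utf8_error_offset <- function(x) {
  r <- charToRaw(x)
  last_ok <- 0L
  for (i in seq_along(r)) {
    if (validUTF8(rawToChar(r[seq_len(i)]))) {
      last_ok <- i
    } else if (i - last_ok > 3L) {
      return(last_ok + 1L)
    }
  }
  last_ok + 1L
}

read_contractions <- function() {
  path <- system.file("extdata", "contractions.tsv", package = "phqminer",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character")
}

#' Tokenize normalized text
#'
#' Splits on whitespace, strips punctuation from token edges (internal
#' apostrophes and underscores survive, so joined multiword lexicon entries
#' stay single tokens), and drops empty tokens.
#'
#' @param text A single normalized string (see [normalize_text()]).
#' @return Character vector of tokens.
#' @examples
#' tokenize("i feel hopeless.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) return(character(0))
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  toks <- gsub("^[^[:alnum:]_]+|[^[:alnum:]_]+$", "", toks)
  toks[nzchar(toks)]
}

#' Closed-class (function) words
#'
#' The deterministic part-of-speech backend shipped with the package: a list
#' of common English determiners, pronouns, prepositions, conjunctions,
#' auxiliaries and other closed-class words. Tokens on this list are tagged
#' `function`; everything else is treated as an open-class content word
#' (noun/verb/adjective/adverb), which is the only distinction the pipeline
#' needs.
#'
#' @return Character vector of function words.
#' @export
function_words <- function() {
  c("the", "a", "an", "and", "or", "but", "if", "then", "than", "because",
    "so", "as", "of", "in", "on", "at", "to", "from", "by", "with",
    "without", "about", "into", "onto", "over", "under", "through", "for",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
    "them", "my", "your", "his", "its", "our", "their", "this", "that",
    "these", "those", "who", "whom", "which", "what", "when", "where",
    "why", "how", "is", "am", "are", "was", "were", "be", "been", "being",
    "do", "does", "did", "have", "has", "had", "will", "would", "shall",
    "should", "can", "could", "may", "might", "must", "not", "no", "nor",
    "there", "here", "up", "down", "out", "off", "again", "once", "all",
    "any", "both", "each", "few", "more", "most", "other", "some", "such",
    "only", "own", "same", "too", "very", "just", "also", "while", "until",
    "yet", "per", "via")
}

#' Part-of-speech taggers
#'
#' A tagger is a function mapping a character vector of tokens to a character
#' vector of tags. Two deterministic backends ship with the package:
#' `default_tagger()` tags words on the [function_words()] list as
#' `"function"` and all other tokens as content (`"noun"` as the open-class
#' default); `dictionary_tagger()` wraps an explicit token-to-tag table for
#' tests and custom vocabularies.
#'
#' @param tags Named character vector, token -> tag (tags such as `"noun"`,
#'   `"verb"`, `"adj"`, `"adv"`, `"function"`).
#' @param default Tag for tokens missing from `tags`.
#' @return A tagger function.
#' @export
default_tagger <- function() {
  fw <- function_words()
  function(tokens) ifelse(tokens %in% fw, "function", "noun")
}

#' @rdname default_tagger
#' @export
dictionary_tagger <- function(tags, default = "noun") {
  stopifnot(is.character(tags), !is.null(names(tags)))
  function(tokens) {
    out <- unname(tags[tokens])
    out[is.na(out)] <- default
    out
  }
}

CONTENT_TAGS <- c("noun", "verb", "adj", "adv", "adjective", "adverb")

#' Keep content words
#'
#' Retains the tokens the tagger labels noun, verb, adjective or adverb, in
#' their original order. With `tagger = NULL` (no backend available) the
#' token list is returned unchanged with a warning.
#'
#' @param tokens Character vector from [tokenize()].
#' @param tagger A tagger function (see [default_tagger()]).
#' @return Character vector, a subsequence of `tokens`.
#' @export
pos_filter <- function(tokens, tagger = default_tagger()) {
  stopifnot(is.character(tokens))
  if (is.null(tagger)) {
    warn("no POS tagger available; returning tokens unfiltered.")
    return(tokens)
  }
  if (length(tokens) == 0) return(character(0))
  tokens[tagger(tokens) %in% CONTENT_TAGS]
}

#' Preprocess a corpus tibble
#'
#' Applies [normalize_text()], [tokenize()] and [pos_filter()] to every post,
#' returning the corpus with `tokens` and `content_tokens` list-columns.
#' Sentence counts (split on `.?!`) are attached for corpus statistics.
#'
#' @param posts Tibble with columns `post_id`, `text`.
#' @param tagger POS backend passed to [pos_filter()].
#' @param contractions Passed to [normalize_text()].
#' @return The input tibble with list-columns `tokens`, `content_tokens` and
#'   an integer `n_sentences` column.
#' @export
preprocess_corpus <- function(posts, tagger = default_tagger(),
                              contractions = NULL) {
  stopifnot(is.data.frame(posts), all(c("post_id", "text") %in% names(posts)))
  if (anyDuplicated(posts$post_id)) abort("post_id must be unique within a corpus.")
  norm <- normalize_text(posts$text, contractions = contractions)
  toks <- lapply(norm, tokenize)
  posts$tokens <- toks
  posts$content_tokens <- lapply(toks, pos_filter, tagger = tagger)
  posts$n_sentences <- vapply(posts$text, function(x) {
    max(1L, length(strsplit(x, "[.?!]+\\s+", perl = TRUE)[[1]]))
  }, 1L, USE.NAMES = FALSE)
  tibble::as_tibble(posts)
}
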