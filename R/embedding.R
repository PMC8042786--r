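#' Word-vector tables
#'
#' A `word_vector_table` holds an m x delta matrix of word vectors with the
#' vocabulary as row names. `read_word_vectors()` parses the two common
#' plain-text dialects: word2vec text (first line a `m delta` header) and
#' GloVe text (no header); the dialect is auto-detected. Duplicate terms keep
#' their first occurrence with a warning; ragged rows are an error naming
#' the line.
#'
#' @param path Path to a vectors text file.
#' @param expected_dim If given, error unless the file's dimension matches.
#' @return A `word_vector_table`.
#' @export
read_word_vectors <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) abort(paste0("word-vector file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("word-vector file is empty.")
  first <- strsplit(trimws(lines[1]), "\\s+", perl = TRUE)[[1]]
  start <- 1L
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    start <- 2L  # word2vec header "m delta"
  }
  body <- lines[seq(start, length(lines))]
  parts <- strsplit(trimws(body), "\\s+", perl = TRUE)
  widths <- vapply(parts, length, 1L)
  dim <- widths[1] - 1L
  if (dim < 1) abort("word-vector rows must contain a term and at least one value.")
  bad <- which(widths != widths[1])
  if (length(bad) > 0) {
    abort(paste0("ragged word-vector row at line ", bad[1] + start - 1L,
                 " (expected ", dim, " values)."))
  }
  if (!is.null(expected_dim) && dim != expected_dim) {
    abort(paste0("word-vector dimension ", dim, " does not match expected_dim ",
                 expected_dim, "."))
  }
  terms <- vapply(parts, `[[`, "", 1L)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, -1L))), ncol = dim, byrow = TRUE)
  )
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    abort(paste0("non-numeric value in word-vector row at line ", bad + start - 1L, "."))
  }
  dup <- duplicated(terms)
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicated term(s) in word-vector file; keeping first."))
    vals <- vals[!dup, , drop = FALSE]
    terms <- terms[!dup]
  }
  word_vector_table(vals, terms)
}

#' @rdname read_word_vectors
#' @param vectors Numeric m x delta matrix.
#' @param vocabulary Character vector of m unique terms.
#' @export
word_vector_table <- function(vectors, vocabulary) {
  vectors <- as.matrix(vectors)
  stopifnot(is.numeric(vectors), length(vocabulary) == nrow(vectors))
  if (anyDuplicated(vocabulary)) abort("word-vector vocabulary has duplicates.")
  if (!all(is.finite(vectors))) abort("word vectors must be finite.")
  rownames(vectors) <- vocabulary
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "word_vector_table")
}

#' @rdname read_word_vectors
#' @param table A `word_vector_table`.
#' @param header Write the word2vec `m delta` header line? Default `TRUE`.
#' @export
write_word_vectors <- function(table, path, header = TRUE) {
  stopifnot(inherits(table, "word_vector_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  v <- table$vectors
  if (header) writeLines(paste(nrow(v), ncol(v)), con)
  writeLines(paste(rownames(v),
                   apply(v, 1, function(r) paste(formatC(r, digits = 8, format = "g"),
                                                 collapse = " "))), con)
  invisible(path)
}

#' @export
print.word_vector_table <- function(x, ...) {
  cat("<word_vector_table> ", nrow(x$vectors), " terms, dim ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Build the emotion vocabulary
#'
#' The embedding vocabulary W of the pipeline: the union of every post's
#' content words (POS-filtered tokens) and their lexical-database expansions
#' (synonyms, hypernyms, hyponyms, antonyms; top `top_k` per word and
#' relation). Provenance distinguishes corpus content words from expansion
#' terms.
#'
#' @param corpus Preprocessed corpus from [preprocess_corpus()] (needs the
#'   `content_tokens` list-column).
#' @param db A [lexdb()].
#' @param top_k Expansion depth per (word, relation), as in
#'   [expand_lexicon()].
#' @return Tibble with columns `word`, `source`
#'   (`corpus-content-word`/`lexical-expansion`).
#' @export
build_emotion_vocabulary <- function(corpus, db = lexdb(), top_k = 5) {
  stopifnot(is.data.frame(corpus), "content_tokens" %in% names(corpus))
  base <- unique(unlist(corpus$content_tokens))
  if (length(base) == 0) {
    return(tibble::tibble(word = character(0), source = character(0)))
  }
  expanded <- unique(unlist(lapply(base, function(w) {
    unlist(lapply(LEXDB_RELATIONS, function(rel) head(lexdb_lookup(db, w, rel), top_k)))
  })))
  expanded <- setdiff(expanded, base)
  tibble::tibble(
    word = c(base, expanded),
    source = c(rep("corpus-content-word", length(base)),
               rep("lexical-expansion", length(expanded)))
  )
}

#' Train corpus word vectors by PPMI factorisation
#'
#' Desk-scale distributional embedding: counts symmetric windowed
#' co-occurrences over the vocabulary, applies the positive pointwise mutual
#' information (PPMI) transform, and takes a rank-`dim` truncated SVD; the
#' word vectors are the left singular vectors scaled by the square root of
#' the singular values. Deterministic given its inputs (singular-vector signs
#' are fixed by making each component's largest-magnitude loading positive).
#'
#' @param corpus Preprocessed corpus (uses the `tokens` list-column).
#' @param vocabulary Optional character vector restricting the vocabulary
#'   (e.g. from [build_emotion_vocabulary()]); default: all corpus tokens.
#' @param dim Embedding dimension (>= 2 and <= vocabulary size).
#' @param window Symmetric context window size in tokens.
#' @param seed Unused by the deterministic factorisation; kept so callers can
#'   treat all embedding sources uniformly.
#' @return A `word_vector_table`.
#' @export
train_domain_embedding <- function(corpus, vocabulary = NULL, dim = 50,
                                   window = 5, seed = NULL) {
  stopifnot(is.data.frame(corpus), "tokens" %in% names(corpus))
  if (nrow(corpus) == 0) abort("cannot train an embedding on an empty corpus.")
  vocabulary <- vocabulary %||% sort(unique(unlist(corpus$tokens)))
  m <- length(vocabulary)
  if (dim < 2) abort("embedding dim must be at least 2.")
  if (dim > m) abort(paste0("embedding dim ", dim, " exceeds vocabulary size ", m, "."))
  counts <- cooccurrence_counts(corpus$tokens, vocabulary, window)
  ppmi <- ppmi_transform(counts)
  sv <- svd(ppmi, nu = dim, nv = 0)
  d <- sv$d[seq_len(dim)]
  u <- sv$u
  # fix the SVD sign ambiguity so repeated runs are bit-identical
  for (j in seq_len(dim)) {
    piv <- which.max(abs(u[, j]))
    if (u[piv, j] < 0) u[, j] <- -u[, j]
  }
  vecs <- u %*% diag(sqrt(pmax(d, 0)), dim)
  word_vector_table(vecs, vocabulary)
}

# Symmetric windowed co-occurrence counts; returns a dense m x m matrix.
cooccurrence_counts <- function(token_lists, vocabulary, window) {
  m <- length(vocabulary)
  counts <- matrix(0, m, m, dimnames = list(vocabulary, vocabulary))
  for (toks in token_lists) {
    idx <- match(toks, vocabulary)
    n <- length(idx)
    if (n < 2) next
    for (off in seq_len(min(window, n - 1))) {
      a <- idx[seq_len(n - off)]
      b <- idx[seq(off + 1, n)]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      tab <- table(a[ok], b[ok])
      ai <- as.integer(rownames(tab))
      bi <- as.integer(colnames(tab))
      counts[ai, bi] <- counts[ai, bi] + tab
    }
  }
  counts + t(counts)
}

# Positive pointwise mutual information; zero-count pairs map to 0.
ppmi_transform <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  pmi <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  pos <- counts > 0 & rs[row(counts)] > 0 & cs[col(counts)] > 0
  pmi[pos] <- log(counts[pos] * total /
                    (rs[row(counts)[pos]] * cs[col(counts)[pos]]))
  pmax(pmi, 0)
}

#' Mean-pool token vectors
#'
#' The sentence/post embedding of the pipeline: the element-wise mean of the
#' vectors of in-vocabulary tokens. Out-of-vocabulary tokens are ignored; an
#' empty or all-OOV input yields the zero vector. The number of OOV tokens is
#' attached as attribute `n_oov`.
#'
#' @param tokens Character vector.
#' @param table A `word_vector_table`.
#' @return Numeric vector of length `table$dim`.
#' @export
embed_tokens <- function(tokens, table) {
  stopifnot(inherits(table, "word_vector_table"))
  if (nrow(table$vectors) == 0) abort("word-vector table is empty.")
  idx <- match(tokens, rownames(table$vectors))
  oov <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  out <- if (length(idx) == 0) {
    numeric(table$dim)
  } else {
    colMeans(table$vectors[idx, , drop = FALSE])
  }
  attr(out, "n_oov") <- oov
  out
}
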