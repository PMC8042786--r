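#' Cosine similarity
#'
#' `x . y / (||x|| ||y||)`, with the convention that a zero-norm argument
#' yields 0 (an empty or all-OOV post is similar to nothing).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("cosine_similarity requires finite inputs.")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Score posts against the nine symptom lexicons
#'
#' For every post, embeds its content tokens (mean word vector) and each
#' symptom lexicon's pseudo-document, and records their cosine similarity.
#' Negative cosines are clipped to 0 so scores live on the `[0, 1]` scale
#' used downstream (rescaling `(1 + cos)/2` was rejected: it would score
#' unrelated, orthogonal text at 0.5). Posts with an all-zero embedding get
#' a zero profile with a warning.
#'
#' @param corpus Preprocessed corpus from [preprocess_corpus()].
#' @param lexicon A `phq_lexicon` covering S1..S9.
#' @param table A `word_vector_table`.
#' @param use_content_tokens Embed POS-filtered `content_tokens` (default,
#'   matching the emotion-vocabulary construction) or raw `tokens`.
#' @param include_antonyms Passed to [lexicon_document()].
#' @return A tibble with `post_id` and numeric score columns `S1`..`S9`,
#'   each in `[0, 1]`.
#' @export
similarity_profiles <- function(corpus, lexicon, table,
                                use_content_tokens = TRUE,
                                include_antonyms = FALSE) {
  stopifnot(is.data.frame(corpus), is.data.frame(lexicon))
  col <- if (use_content_tokens) "content_tokens" else "tokens"
  if (!col %in% names(corpus)) {
    abort(paste0("corpus lacks the '", col, "' column; run preprocess_corpus() first."))
  }
  missing <- setdiff(SYMPTOM_IDS, unique(lexicon$symptom_id))
  if (length(missing) > 0) {
    abort(paste0("lexicon does not cover symptom(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  lex_emb <- vapply(SYMPTOM_IDS, function(sid) {
    embed_tokens(lexicon_document(lexicon, sid, include_antonyms), table)
  }, numeric(table$dim))
  scores <- matrix(0, nrow(corpus), 9, dimnames = list(NULL, SYMPTOM_IDS))
  n_zero <- 0L
  for (i in seq_len(nrow(corpus))) {
    x <- embed_tokens(corpus[[col]][[i]], table)
    if (all(x == 0)) {
      n_zero <- n_zero + 1L
      next
    }
    scores[i, ] <- vapply(SYMPTOM_IDS, function(sid) {
      max(0, cosine_similarity(x, lex_emb[, sid]))
    }, 0)
  }
  if (n_zero > 0) {
    warn(paste0(n_zero, " post(s) had an all-zero embedding; zero profiles assigned."))
  }
  dplyr::bind_cols(tibble::tibble(post_id = corpus$post_id),
                   tibble::as_tibble(scores))
}

#' Binarize similarity profiles into a label matrix
#'
#' A symptom is marked present (1) when its score is at or above the
#' threshold; absent (0) otherwise.
#'
#' @param profiles Tibble from [similarity_profiles()].
#' @param threshold Single number in `[0, 1]` applied to all symptoms, or a
#'   length-9 vector of per-symptom thresholds (order S1..S9).
#' @return A label-matrix tibble (`post_id`, `S1`..`S9` in 0/1).
#' @export
binarize <- function(profiles, threshold = 0.5) {
  stopifnot(is.data.frame(profiles), all(SYMPTOM_IDS %in% names(profiles)))
  if (!length(threshold) %in% c(1L, 9L)) {
    abort("threshold must be a single value or a length-9 vector.")
  }
  if (any(threshold < 0 | threshold > 1)) abort("thresholds must lie in [0, 1].")
  thr <- rep_len(threshold, 9L)
  scores <- as.matrix(profiles[, SYMPTOM_IDS])
  labels <- sweep(scores, 2, thr, `>=`) * 1L
  out <- dplyr::bind_cols(tibble::tibble(post_id = profiles$post_id),
                          tibble::as_tibble(labels))
  as_label_matrix(out)
}

#' Calibrate per-symptom binarization thresholds on a gold subset
#'
#' Mirrors the study design of anchoring the weak labels to a small
#' human-annotated subset: for each symptom, picks the score threshold
#' maximizing Youden's J statistic (TPR - FPR) on the gold labels, breaking
#' ties toward the lowest threshold. The candidate grid is the symptom's
#' observed scores plus 0. A symptom whose gold labels are single-class gets
#' threshold 0.5 with a warning.
#'
#' @param profiles Tibble from [similarity_profiles()].
#' @param gold Label matrix covering the profiled posts.
#' @return Tibble with columns `symptom_id`, `threshold`, `youden_j`.
#' @export
calibrate_thresholds <- function(profiles, gold) {
  stopifnot(is.data.frame(profiles))
  gold <- as_label_matrix(gold)
  if (!all(profiles$post_id %in% gold$post_id)) {
    abort("gold labels do not cover all profiled posts.")
  }
  gold <- gold[match(profiles$post_id, gold$post_id), ]
  out <- lapply(SYMPTOM_IDS, function(sid) {
    s <- profiles[[sid]]
    y <- gold[[sid]]
    if (length(unique(y)) < 2) {
      warn(paste0("symptom ", sid, " has single-class gold labels; threshold 0.5 assigned."))
      return(tibble::tibble(symptom_id = sid, threshold = 0.5, youden_j = NA_real_))
    }
    grid <- sort(unique(c(0, s)))
    j <- vapply(grid, function(t) {
      pred <- as.integer(s >= t)
      tpr <- sum(pred == 1 & y == 1) / sum(y == 1)
      fpr <- sum(pred == 1 & y == 0) / sum(y == 0)
      tpr - fpr
    }, 0)
    best <- grid[which.max(j)]  # which.max returns the first (lowest) maximizer
    tibble::tibble(symptom_id = sid, threshold = best, youden_j = max(j))
  })
  dplyr::bind_rows(out)
}

#' Run the full weak-labeling pipeline on a corpus
#'
#' Convenience composition: preprocess, score with [similarity_profiles()],
#' binarize. Returns profiles and labels joined on `post_id`.
#'
#' @inheritParams similarity_profiles
#' @param posts Raw corpus tibble (`post_id`, `text`).
#' @param threshold Passed to [binarize()].
#' @param tagger Passed to [preprocess_corpus()].
#' @return List with elements `profiles` (scores tibble) and `labels`
#'   (label-matrix tibble).
#' @export
weak_label_corpus <- function(posts, lexicon, table, threshold = 0.5,
                              tagger = default_tagger(),
                              use_content_tokens = TRUE,
                              include_antonyms = FALSE) {
  corpus <- preprocess_corpus(posts, tagger = tagger)
  profiles <- similarity_profiles(corpus, lexicon, table,
                                  use_content_tokens = use_content_tokens,
                                  include_antonyms = include_antonyms)
  list(profiles = profiles, labels = binarize(profiles, threshold))
}
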