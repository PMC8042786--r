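#' Read and write corpora as JSON lines
#'
#' One post per line: `{"id": ..., "text": ..., "labels": [0/1 x 9]}` with
#' `labels` optional. In strict mode (default) a malformed line raises an
#' error naming the line; in lenient mode it is skipped with a warning.
#'
#' @param path File path.
#' @param strict Error on malformed lines (`TRUE`) or skip them (`FALSE`).
#' @return A tibble with columns `post_id`, `text` and, when any line
#'   carries labels, the nine 0/1 columns `S1`..`S9`.
#' @export
read_corpus_jsonl <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[idx[j]], simplifyVector = TRUE),
                    error = function(e) NULL)
    ok <- !is.null(rec) && !is.null(rec$id) && !is.null(rec$text) &&
      (is.null(rec$labels) || length(rec$labels) == 9)
    if (!ok) {
      msg <- paste0("malformed corpus record at line ", idx[j], ".")
      if (strict) abort(msg)
      warn(paste(msg, "Skipping."))
      next
    }
    recs[[j]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) {
    return(tibble::tibble(post_id = character(0), text = character(0)))
  }
  out <- tibble::tibble(
    post_id = vapply(recs, function(r) as.character(r$id), ""),
    text = vapply(recs, function(r) as.character(r$text), "")
  )
  has_labels <- vapply(recs, function(r) !is.null(r$labels), TRUE)
  if (any(has_labels)) {
    lab <- matrix(NA_integer_, nrow(out), 9, dimnames = list(NULL, SYMPTOM_IDS))
    lab[has_labels, ] <- do.call(rbind, lapply(recs[has_labels],
                                               function(r) as.integer(r$labels)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(lab))
  }
  out
}

#' @rdname read_corpus_jsonl
#' @param posts Tibble with `post_id`, `text` and optionally `S1`..`S9`
#'   columns (or extra columns such as `scores`, written as-is).
#' @export
write_corpus_jsonl <- function(posts, path) {
  stopifnot(is.data.frame(posts), all(c("post_id", "text") %in% names(posts)))
  has_labels <- all(SYMPTOM_IDS %in% names(posts))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    rec <- list(id = posts$post_id[i], text = posts$text[i])
    if (has_labels) {
      rec$labels <- as.integer(unlist(posts[i, SYMPTOM_IDS]))
    }
    if ("scores" %in% names(posts)) rec$scores <- as.numeric(posts$scores[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Label-matrix helpers
#'
#' A label matrix is a tibble with `post_id` plus the nine 0/1 columns
#' `S1`..`S9` in questionnaire order. `as_label_matrix()` validates/coerces;
#' `label_matrix_values()` extracts the bare N x 9 integer matrix.
#'
#' @param x A data frame with `post_id` and `S1`..`S9` columns.
#' @return A validated tibble (or an integer matrix for
#'   `label_matrix_values()`).
#' @export
as_label_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("post_id", SYMPTOM_IDS)
  if (!all(need %in% names(x))) {
    abort(paste0("label matrix is missing column(s): ",
                 paste(setdiff(need, names(x)), collapse = ", "), "."))
  }
  vals <- as.matrix(x[, SYMPTOM_IDS])
  if (!all(vals %in% c(0L, 1L))) abort("label matrix entries must be 0 or 1.")
  tibble::as_tibble(x[, need])
}

#' @rdname as_label_matrix
#' @export
label_matrix_values <- function(x) {
  x <- as_label_matrix(x)
  m <- as.matrix(x[, SYMPTOM_IDS])
  storage.mode(m) <- "integer"
  rownames(m) <- x$post_id
  m
}

#' @rdname as_label_matrix
#' @param path File path for the CSV writer/reader.
#' @export
write_label_csv <- function(x, path) {
  x <- as_label_matrix(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname as_label_matrix
#' @export
read_label_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("label file not found: ", path))
  df <- utils::read.csv(path, colClasses = c(post_id = "character"))
  as_label_matrix(tibble::as_tibble(df))
}
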