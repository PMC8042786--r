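#' ROC curve and AUC for one symptom
#'
#' `roc_auc()` computes the exact area under the ROC curve by the rank (pair
#' counting) formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counting one half.
#' `roc_curve()` returns the full curve at every unique score threshold.
#'
#' @param scores Numeric vector of predicted scores.
#' @param truth Binary 0/1 vector of the same length, containing both
#'   classes.
#' @return `roc_auc()`: a number in `[0, 1]`. `roc_curve()`: a tibble with
#'   `threshold`, `fpr`, `tpr`, both monotone non-decreasing as the
#'   threshold falls.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined: truth contains a single class.")
  }
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) abort("ROC is undefined: truth contains a single class.")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & truth == 1) / n1, 0),
    fpr = vapply(thr, function(t) sum(scores >= t & truth == 0) / n0, 0)
  )
}

#' Per-symptom ROC evaluation and the mean AUC
#'
#' Computes the ROC AUC of each symptom's score column against the true
#' labels and their unweighted mean — the headline metric for comparing
#' architectures. A symptom whose truth is single-class is skipped with a
#' warning; the mean is over the remaining symptoms.
#'
#' @param scores An N x 9 matrix or tibble of scores/probabilities with
#'   columns S1..S9 (a `post_id` column is allowed and ignored).
#' @param truth Matching label matrix (tibble with `post_id` + S1..S9, or a
#'   bare N x 9 matrix aligned by row).
#' @param threshold Operating threshold used for the reported precision and
#'   recall columns (default 0.5).
#' @return A `phq_roc` list: `per_symptom` (tibble: symptom_id, auc,
#'   precision, recall, n_pos, plus a `curve` list-column) and `mean_auc`.
#' @export
mean_roc <- function(scores, truth, threshold = 0.5) {
  s <- if (is.data.frame(scores)) as.matrix(scores[, SYMPTOM_IDS]) else as.matrix(scores)
  colnames(s) <- SYMPTOM_IDS
  y <- if (is.data.frame(truth)) label_matrix_values(truth) else as.matrix(truth)
  stopifnot(nrow(s) == nrow(y), ncol(y) == 9)
  colnames(y) <- SYMPTOM_IDS
  rows <- lapply(SYMPTOM_IDS, function(sid) {
    yk <- y[, sid]
    if (length(unique(yk)) < 2) {
      warn(paste0("symptom ", sid, " is single-class in truth; skipped."))
      return(tibble::tibble(symptom_id = sid, auc = NA_real_,
                            precision = NA_real_, recall = NA_real_,
                            n_pos = sum(yk), curve = list(NULL)))
    }
    sk <- s[, sid]
    pred <- as.integer(sk >= threshold)
    tp <- sum(pred == 1 & yk == 1)
    tibble::tibble(
      symptom_id = sid,
      auc = roc_auc(sk, yk),
      precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
      recall = tp / sum(yk),
      n_pos = sum(yk),
      curve = list(roc_curve(sk, yk))
    )
  })
  per <- dplyr::bind_rows(rows)
  if (all(is.na(per$auc))) abort("all symptoms are single-class; mean AUC undefined.")
  structure(list(per_symptom = per, mean_auc = mean(per$auc, na.rm = TRUE),
                 threshold = threshold),
            class = "phq_roc")
}

#' @export
print.phq_roc <- function(x, ...) {
  cat("<phq_roc> mean AUC ", round(x$mean_auc, 4), " over ",
      sum(!is.na(x$per_symptom$auc)), " symptom(s)\n", sep = "")
  invisible(x)
}

#' @rdname mean_roc
#' @param x,object A `phq_roc`.
#' @param ... Unused.
#' @export
tidy.phq_roc <- function(x, ...) {
  dplyr::select(x$per_symptom, "symptom_id", "auc", "precision", "recall", "n_pos")
}

#' @rdname mean_roc
#' @export
glance.phq_roc <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc,
                 min_auc = min(x$per_symptom$auc, na.rm = TRUE),
                 max_auc = max(x$per_symptom$auc, na.rm = TRUE),
                 n_symptoms = sum(!is.na(x$per_symptom$auc)),
                 threshold = x$threshold)
}

#' @rdname mean_roc
#' @export
autoplot.phq_roc <- function(object, ...) {
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(object$per_symptom)), function(i) {
    cv <- object$per_symptom$curve[[i]]
    if (is.null(cv)) return(NULL)
    dplyr::mutate(cv, symptom_id = object$per_symptom$symptom_id[i])
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::facet_wrap(~symptom_id) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = paste0("Per-symptom ROC (mean AUC ",
                                 round(object$mean_auc, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Render per-token attention weights
#'
#' Turns a post's attention weights into a rendering table (intensity =
#' weight / max weight; the `top_n` heaviest tokens flagged) for inspection
#' of which words triggered the classification. `attention_html()` writes a
#' standalone HTML fragment with per-token background opacity;
#' `autoplot()` draws the same thing with ggplot2.
#'
#' @param tokens Character vector of the model-input tokens.
#' @param weights Attention weights aligned with `tokens` (summing to 1).
#' @param top_n Number of tokens to flag as highlighted.
#' @return An `attention_rendering` tibble with columns `token`, `weight`,
#'   `intensity`, `highlight`.
#' @export
render_attention <- function(tokens, weights, top_n = 5) {
  if (length(tokens) != length(weights)) {
    abort(paste0("tokens (", length(tokens), ") and weights (",
                 length(weights), ") differ in length."))
  }
  stopifnot(length(tokens) > 0, all(weights >= 0))
  out <- tibble::tibble(
    token = tokens,
    weight = as.numeric(weights),
    intensity = if (max(weights) > 0) weights / max(weights) else rep(0, length(weights)),
    highlight = rank(-weights, ties.method = "first") <= top_n
  )
  class(out) <- c("attention_rendering", class(out))
  out
}

#' @rdname render_attention
#' @param rendering An `attention_rendering` (or a list of them).
#' @param path Output HTML file.
#' @param title Page title.
#' @export
attention_html <- function(rendering, path, title = "Attention weights") {
  if (is.data.frame(rendering)) rendering <- list(rendering)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  spans <- vapply(rendering, function(r) {
    paste0("<p>", paste0(
      "<span style=\"background: rgba(214, 96, 77, ", round(r$intensity, 3),
      ");", ifelse(r$highlight, " font-weight: bold;", ""), "\">",
      esc(r$token), "</span>", collapse = " "), "</p>")
  }, "")
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            paste0("<title>", esc(title), "</title>"),
            "<style>body{font-family: sans-serif; line-height: 1.8; margin: 2em;}",
            "span{padding: 1px 2px; border-radius: 3px;}</style></head><body>",
            paste0("<h1>", esc(title), "</h1>"), spans, "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname render_attention
#' @param object An `attention_rendering`.
#' @param ... Unused.
#' @export
autoplot.attention_rendering <- function(object, ...) {
  df <- dplyr::mutate(object, pos = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = 1, fill = .data$intensity)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$token), angle = 90, size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#d6604d",
                                 limits = c(0, 1), name = "intensity") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Per-token attention")
}
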