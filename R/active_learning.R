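#' Select the most informative pool instances
#'
#' Returns the `k` pool ids with the highest acquisition score (predictive
#' entropy), ties broken by ascending post id so selection is deterministic.
#' Asking for more than the pool holds returns the whole pool.
#'
#' @param pool_ids Character vector of candidate post ids.
#' @param scores Numeric vector of acquisition scores aligned with
#'   `pool_ids`.
#' @param k Number of instances to select (>= 1).
#' @return Character vector of selected ids (in selection order).
#' @export
select_batch <- function(pool_ids, scores, k) {
  stopifnot(length(pool_ids) == length(scores), k >= 1)
  if (length(pool_ids) == 0) return(character(0))
  ord <- order(-scores, pool_ids)
  pool_ids[ord][seq_len(min(k, length(pool_ids)))]
}

#' Entropy-based active-learning loop
#'
#' Grows the training set from an unlabeled pool: each round trains a fresh
#' model on the current labeled set, scores the pool by multi-label
#' predictive entropy ([multilabel_entropy()]), selects the `batch_k` most
#' uncertain posts ([select_batch()]; or uniformly at random for the
#' comparison baseline), labels them with the supplied labeler, and moves
#' them into the labeled set. The loop stops when the pool is empty, the
#' round cap is reached, or the validation metric (mean AUC over symptoms)
#' has failed to improve for `metric_patience` consecutive rounds.
#'
#' Retraining is from scratch each round under a seed derived from
#' `(config$seed, round)`, avoiding warm-start confounds.
#'
#' @param x Model input for every post (labeled and pool): an N x dim matrix
#'   with post ids as row names (baseline) or a named list of sequences.
#' @param labeler Function `character ids -> label-matrix tibble` providing
#'   labels on demand. In the weak-supervision pipeline this wraps
#'   [binarize()] output; substituting the ground truth simulates a human
#'   annotator.
#' @param initial_ids Ids of the initially labeled posts (nonempty).
#' @param val_x,val_labels Held-out validation inputs and true labels used
#'   for the per-round metric (not part of pool or labeled set).
#' @param model_kind Architecture, as in [train_model()].
#' @param config A [train_config()].
#' @param rounds Maximum number of acquisition rounds.
#' @param batch_k Instances acquired per round.
#' @param acquisition `"entropy"` (default) or `"random"`.
#' @param metric_patience Stop after this many rounds without validation
#'   improvement; default 2.
#' @return List of class `phq_al` with the final `model`, `history` (tibble:
#'   round, n_labeled, mean_entropy_selected, val_auc, selected ids
#'   list-column) and the final `labeled_ids`/`pool_ids`.
#' @export
active_loop <- function(x, labeler, initial_ids, val_x, val_labels,
                        model_kind = "baseline", config = train_config(),
                        rounds = 10, batch_k = 100,
                        acquisition = c("entropy", "random"),
                        metric_patience = 2) {
  acquisition <- match.arg(acquisition)
  all_ids <- if (is.matrix(x)) rownames(x) else names(x)
  if (is.null(all_ids)) abort("x must carry post ids (row names or list names).")
  stopifnot(length(initial_ids) > 0, all(initial_ids %in% all_ids))
  take <- function(ids) if (is.matrix(x)) x[ids, , drop = FALSE] else x[ids]
  val_truth <- label_matrix_values(val_labels)

  labeled_ids <- sort(unique(initial_ids))
  pool_ids <- sort(setdiff(all_ids, labeled_ids))
  labels <- labeler(labeled_ids)
  history <- list()
  best_metric <- -Inf
  wait <- 0L
  model <- NULL

  for (r in seq_len(rounds)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + r)
    model <- train_model(take(labeled_ids),
                         labels[match(labeled_ids, labels$post_id), ],
                         model_kind, cfg)
    val_probs <- predict_proba(model, val_x)
    val_auc <- suppressWarnings(mean_roc(val_probs, val_truth)$mean_auc)

    selected <- character(0)
    mean_ent <- NA_real_
    if (length(pool_ids) > 0) {
      if (acquisition == "entropy") {
        ent <- multilabel_entropy(predict_proba(model, take(pool_ids)))
        selected <- select_batch(pool_ids, ent, batch_k)
        mean_ent <- mean(ent[match(selected, pool_ids)])
      } else {
        selected <- with_rng(derive_seed(config$seed, 200L + r), {
          sample(pool_ids, min(batch_k, length(pool_ids)))
        })
      }
    }
    history[[r]] <- tibble::tibble(
      round = r, n_labeled = length(labeled_ids),
      mean_entropy_selected = mean_ent, val_auc = val_auc,
      selected = list(selected)
    )
    improved <- val_auc > best_metric + 1e-6
    if (improved) {
      best_metric <- val_auc
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (length(pool_ids) == 0 || wait >= metric_patience) break
    new_labels <- labeler(selected)
    labels <- dplyr::bind_rows(labels, new_labels)
    labeled_ids <- sort(c(labeled_ids, selected))
    pool_ids <- sort(setdiff(pool_ids, selected))
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 labeled_ids = labeled_ids, pool_ids = pool_ids,
                 acquisition = acquisition),
            class = "phq_al")
}

#' @export
print.phq_al <- function(x, ...) {
  cat("<phq_al> ", x$acquisition, " acquisition, ", nrow(x$history),
      " round(s), ", length(x$labeled_ids), " labeled / ",
      length(x$pool_ids), " pooled\n", sep = "")
  invisible(x)
}

#' @rdname active_loop
#' @param object,x A `phq_al` result.
#' @param ... Unused.
#' @export
tidy.phq_al <- function(x, ...) {
  dplyr::select(x$history, "round", "n_labeled", "mean_entropy_selected", "val_auc")
}

#' @rdname active_loop
#' @export
glance.phq_al <- function(x, ...) {
  tibble::tibble(acquisition = x$acquisition, rounds = nrow(x$history),
                 n_labeled = length(x$labeled_ids),
                 n_pool = length(x$pool_ids),
                 best_val_auc = max(x$history$val_auc, na.rm = TRUE))
}
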