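# Gradient-based trainer for the four architectures. Gradients are derived
# analytically (backprop / backprop-through-time) and checked against
# numerical differentiation in the test suite.

#' Training configuration
#'
#' Hyperparameters of the trainer. Defaults follow the training protocol the
#' pipeline was designed with: Adam at a static learning rate of 0.0005,
#' dropout 0.5 on the pooled representation feeding the output layer,
#' gradient-norm clipping, and early stopping on validation loss.
#'
#' @param learning_rate Adam step size (static; default 0.0005).
#' @param dropout Dropout rate on the pooled state before the output layer,
#'   in `[0, 1)`; default 0.5.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement.
#' @param grad_clip_norm Global gradient-norm clip; `Inf` disables.
#' @param val_fraction Fraction of the training set held out for the
#'   early-stopping validation loss.
#' @param hidden_size Recurrent state size H.
#' @param attention_size Attention projection size (default `2 * hidden_size`).
#' @param min_delta Minimum validation-loss improvement that resets patience.
#' @param seed Integer seed governing weight init, batch order, dropout and
#'   the validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, dropout = 0.5, max_epochs = 30,
                         batch_size = 32, patience = 10, grad_clip_norm = 1,
                         val_fraction = 0.2, hidden_size = 16,
                         attention_size = NULL, min_delta = 1e-4, seed = 1) {
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1, max_epochs >= 1,
            batch_size >= 1, patience >= 1, grad_clip_norm > 0,
            val_fraction >= 0, val_fraction < 1, hidden_size >= 1)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 grad_clip_norm = grad_clip_norm,
                 val_fraction = val_fraction,
                 hidden_size = as.integer(hidden_size),
                 attention_size = attention_size,
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Post representations for the models
#'
#' `post_mean_embeddings()` builds the baseline's input: one mean-pooled
#' vector per post. `post_sequences()` builds the recurrent models' input:
#' one token-vector matrix per post, truncated to `max_len` (default: the
#' 95th percentile of this corpus's sequence lengths). Out-of-vocabulary
#' tokens are dropped; a post with no usable tokens becomes a single
#' zero-vector step.
#'
#' @param corpus Preprocessed corpus from [preprocess_corpus()].
#' @param table A `word_vector_table`.
#' @param use_content_tokens Use POS-filtered tokens (default) or all tokens.
#' @param max_len Sequence truncation length; `NULL` for the 95th-percentile
#'   rule.
#' @return A numeric N x dim matrix, or a list of T_i x dim matrices with
#'   attribute `tokens` (the kept token strings per post).
#' @export
post_mean_embeddings <- function(corpus, table, use_content_tokens = TRUE) {
  col <- if (use_content_tokens) "content_tokens" else "tokens"
  stopifnot(is.data.frame(corpus), col %in% names(corpus))
  out <- t(vapply(corpus[[col]], function(tk) as.numeric(embed_tokens(tk, table)),
                  numeric(table$dim)))
  rownames(out) <- corpus$post_id
  out
}

#' @rdname post_mean_embeddings
#' @export
post_sequences <- function(corpus, table, use_content_tokens = TRUE,
                           max_len = NULL) {
  col <- if (use_content_tokens) "content_tokens" else "tokens"
  stopifnot(is.data.frame(corpus), col %in% names(corpus))
  vocab <- rownames(table$vectors)
  kept <- lapply(corpus[[col]], function(tk) tk[tk %in% vocab])
  if (is.null(max_len)) {
    lens <- pmax(1L, lengths(kept))
    max_len <- max(1L, ceiling(quantile(lens, 0.95, names = FALSE)))
  }
  kept <- lapply(kept, function(tk) head(tk, max_len))
  seqs <- lapply(kept, function(tk) {
    if (length(tk) == 0) matrix(0, 1, table$dim)
    else table$vectors[tk, , drop = FALSE]
  })
  names(seqs) <- corpus$post_id
  attr(seqs, "tokens") <- kept
  attr(seqs, "max_len") <- max_len
  seqs
}

# ---- batched forward/backward ------------------------------------------------
# The per-step LSTM recursions run in compiled code (src/lstm_core.cpp);
# attention and pooling are vectorised over all (batch, position) pairs here.

# Pack a list of sequences into a B x d x T array plus a mask.
pack_batch <- function(seqs) {
  B <- length(seqs)
  lens <- vapply(seqs, nrow, 1L)
  T_ <- max(lens)
  d <- ncol(seqs[[1]])
  X <- array(0, c(B, d, T_))
  for (b in seq_len(B)) {
    X[b, , seq_len(lens[b])] <- t(seqs[[b]])
  }
  mask <- outer(lens, seq_len(T_), `>=`) * 1
  list(X = X, mask = mask, lens = lens, B = B, T_ = T_, d = d)
}

dir_weights <- function(params, prefix) {
  list(W = cbind(params[[paste0(prefix, "W_i")]], params[[paste0(prefix, "W_f")]],
                 params[[paste0(prefix, "W_o")]], params[[paste0(prefix, "W_c")]]),
       U = cbind(params[[paste0(prefix, "U_i")]], params[[paste0(prefix, "U_f")]],
                 params[[paste0(prefix, "U_o")]], params[[paste0(prefix, "U_c")]]))
}

split_dir_grads <- function(gW, gU, H, prefix) {
  out <- list()
  for (k in seq_along(c("i", "f", "o", "c"))) {
    g <- c("i", "f", "o", "c")[k]
    cols <- (k - 1L) * H + seq_len(H)
    out[[paste0(prefix, "W_", g)]] <- gW[, cols, drop = FALSE]
    out[[paste0(prefix, "U_", g)]] <- gU[, cols, drop = FALSE]
  }
  out
}

# (B, H, T) state cube -> (B*T) x H matrix with row index b + (pos-1)*B.
flatten_states <- function(states) {
  d <- dim(states)
  matrix(aperm(states, c(1, 3, 2)), d[1] * d[3], d[2])
}

# Sum a (B*T) x D row-block matrix over positions -> B x D.
sum_over_positions <- function(M, B, T_) {
  out <- matrix(0, B, ncol(M))
  for (pos in seq_len(T_)) {
    out <- out + M[(pos - 1L) * B + seq_len(B), , drop = FALSE]
  }
  out
}

# Full forward pass on a packed batch. drop_mask: B x D inverted-dropout
# mask (NULL at prediction time). Returns probs and caches.
forward_batch <- function(params, kind, batch, drop_mask = NULL) {
  if (kind == "baseline") abort("forward_batch is for recurrent models.")
  B <- batch$B; T_ <- batch$T_
  wf <- dir_weights(params, "fwd.")
  fwd <- lstm_dir_forward_cpp(batch$X, batch$mask, wf$W, wf$U, FALSE)
  bwd <- NULL
  if (kind %in% c("bilstm", "bilstm_attention")) {
    wb <- dir_weights(params, "bwd.")
    bwd <- lstm_dir_forward_cpp(batch$X, batch$mask, wb$W, wb$U, TRUE)
    S <- cbind(flatten_states(fwd$states), flatten_states(bwd$states))
  } else {
    S <- flatten_states(fwd$states)
  }
  att <- NULL
  if (kind == "bilstm_attention") {
    v <- tanh(sweep(S %*% params$Wa, 2, params$ba, `+`))
    sc <- matrix(drop(v %*% params$ua), B, T_)
    sc[batch$mask == 0] <- -Inf
    sc <- sc - apply(sc, 1, max)
    e <- exp(sc)
    alpha <- e / rowSums(e)
    pooled <- sum_over_positions(as.numeric(alpha) * S, B, T_)
    att <- list(v = v, alpha = alpha)
  } else {
    pooled <- sum_over_positions(as.numeric(batch$mask) * S, B, T_) / batch$lens
  }
  dropped <- if (is.null(drop_mask)) pooled else pooled * drop_mask
  probs <- sigmoid(sweep(dropped %*% params$Wo, 2, params$bo, `+`))
  list(probs = probs, pooled = pooled, dropped = dropped, S = S,
       fwd = fwd, bwd = bwd, att = att)
}

# Backward pass matching forward_batch. y: B x K. Returns flat grad list.
backward_batch <- function(params, kind, batch, fw, y, drop_mask = NULL) {
  B <- batch$B; T_ <- batch$T_
  H <- ncol(params[["fwd.U_i"]])
  S <- fw$S
  dlogits <- (fw$probs - y) / B
  grads <- list(
    Wo = crossprod(fw$dropped, dlogits),
    bo = colSums(dlogits)
  )
  dpooled <- tcrossprod(dlogits, params$Wo)
  if (!is.null(drop_mask)) dpooled <- dpooled * drop_mask
  dP_rep <- dpooled[rep(seq_len(B), T_), , drop = FALSE]  # rows align with S
  if (kind == "bilstm_attention") {
    alpha <- fw$att$alpha
    dS <- as.numeric(alpha) * dP_rep
    dalpha <- matrix(rowSums(dP_rep * S), B, T_)
    ds <- alpha * (dalpha - rowSums(alpha * dalpha))  # softmax backward
    dsv <- as.numeric(ds)
    v <- fw$att$v
    dv_pre <- outer(dsv, params$ua) * (1 - v^2)
    grads$Wa <- crossprod(S, dv_pre)
    grads$ba <- colSums(dv_pre)
    grads$ua <- colSums(v * dsv)
    dS <- dS + tcrossprod(dv_pre, params$Wa)
  } else {
    dS <- (as.numeric(batch$mask) / rep(batch$lens, T_)) * dP_rep
  }
  # (B*T) x D -> (B, D, T) cube for the compiled backward pass
  d_cube <- aperm(array(dS, c(B, T_, ncol(S))), c(1, 3, 2))
  wf <- dir_weights(params, "fwd.")
  if (kind == "lstm") {
    bk <- lstm_dir_backward_cpp(batch$X, batch$mask, wf$U, fw$fwd, d_cube, FALSE)
    grads <- c(grads, split_dir_grads(bk$gW, bk$gU, H, "fwd."))
  } else {
    wb <- dir_weights(params, "bwd.")
    d_fwd <- d_cube[, seq_len(H), , drop = FALSE]
    d_bwd <- d_cube[, H + seq_len(H), , drop = FALSE]
    bf <- lstm_dir_backward_cpp(batch$X, batch$mask, wf$U, fw$fwd, d_fwd, FALSE)
    bb <- lstm_dir_backward_cpp(batch$X, batch$mask, wb$U, fw$bwd, d_bwd, TRUE)
    grads <- c(grads,
               split_dir_grads(bf$gW, bf$gU, H, "fwd."),
               split_dir_grads(bb$gW, bb$gU, H, "bwd."))
  }
  grads
}

# Baseline forward with cache / backward.
baseline_forward_cache <- function(params, x, drop_mask = NULL) {
  h1 <- relu(sweep(x %*% params$W1, 2, params$b1, `+`))
  h2 <- relu(sweep(h1 %*% params$W2, 2, params$b2, `+`))
  h3 <- relu(sweep(h2 %*% params$W3, 2, params$b3, `+`))
  h3d <- if (is.null(drop_mask)) h3 else h3 * drop_mask
  probs <- sigmoid(sweep(h3d %*% params$W4, 2, params$b4, `+`))
  list(probs = probs, h1 = h1, h2 = h2, h3 = h3, h3d = h3d)
}

baseline_backward <- function(params, x, fw, y, drop_mask = NULL) {
  B <- nrow(x)
  dlogits <- (fw$probs - y) / B
  g <- list(W4 = crossprod(fw$h3d, dlogits), b4 = colSums(dlogits))
  dh3 <- tcrossprod(dlogits, params$W4)
  if (!is.null(drop_mask)) dh3 <- dh3 * drop_mask
  dh3 <- dh3 * (fw$h3 > 0)
  g$W3 <- crossprod(fw$h2, dh3); g$b3 <- colSums(dh3)
  dh2 <- tcrossprod(dh3, params$W3) * (fw$h2 > 0)
  g$W2 <- crossprod(fw$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- tcrossprod(dh2, params$W2) * (fw$h1 > 0)
  g$W1 <- crossprod(x, dh1); g$b1 <- colSums(dh1)
  g
}

# ---- optimiser ---------------------------------------------------------------

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (total > max_norm && total > 0) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- trainer -----------------------------------------------------------------

#' Train a symptom classifier
#'
#' Fits one of the four architectures to multi-label symptom data with Adam
#' (static learning rate), dropout on the pooled representation, global
#' gradient-norm clipping and early stopping on a held-out validation split.
#' Training is deterministic given `config$seed` (single-threaded BLAS
#' assumed). A non-finite loss aborts with a diagnostic.
#'
#' @param x For `kind = "baseline"`: an N x input_dim matrix of post
#'   embeddings (see [post_mean_embeddings()]). Otherwise: a list of N
#'   token-vector sequences (see [post_sequences()]).
#' @param y N x 9 binary label matrix (or label-matrix tibble; rows must
#'   align with `x`).
#' @param kind Architecture, as in [init_params()].
#' @param config A [train_config()].
#' @return A fitted `phq_model` with the per-epoch training log.
#' @export
train_model <- function(x, y, kind = c("baseline", "lstm", "bilstm",
                                       "bilstm_attention"),
                        config = train_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "train_config"))
  if (is.data.frame(y)) y <- label_matrix_values(y)
  y <- as.matrix(y)
  n <- if (kind == "baseline") nrow(x) else length(x)
  stopifnot(nrow(y) == n)
  if (all(y == y[1, 1])) abort("training labels are single-class everywhere.")
  input_dim <- if (kind == "baseline") ncol(x) else ncol(x[[1]])

  with_rng(derive_seed(config$seed, 13L), {
    base_rate <- pmin(pmax(colMeans(y), 1e-3), 1 - 1e-3)
    params <- init_params(kind, input_dim, hidden_size = config$hidden_size,
                          attention_size = config$attention_size,
                          n_outputs = ncol(y),
                          output_bias = log(base_rate / (1 - base_rate)),
                          seed = config$seed)
    a_kind <- attr(params, "kind")
    opt <- adam_init(params)

    n_val <- floor(config$val_fraction * n)
    use_val <- n_val >= 2
    val_idx <- if (use_val) sort(sample(n, n_val)) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    eval_loss <- function(p, idx) {
      if (length(idx) == 0) return(NA_real_)
      probs <- predict_core(p, kind, x, idx)
      cross_entropy_loss(y[idx, , drop = FALSE], probs)
    }

    best <- list(params = params, val = Inf, epoch = 0L)
    log <- vector("list", config$max_epochs)
    wait <- 0L
    keep <- 1 - config$dropout
    D <- if (kind == "baseline") 10L
         else if (kind == "lstm") config$hidden_size
         else 2L * config$hidden_size

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        B <- length(idx)
        drop_mask <- if (config$dropout > 0) {
          matrix(rbinom(B * D, 1, keep) / keep, B, D)
        } else NULL
        yb <- y[idx, , drop = FALSE]
        if (kind == "baseline") {
          xb <- x[idx, , drop = FALSE]
          fw <- baseline_forward_cache(params, xb, drop_mask)
          loss <- cross_entropy_loss(yb, fw$probs)
          grads <- baseline_backward(params, xb, fw, yb, drop_mask)
        } else {
          batch <- pack_batch(x[idx])
          fw <- forward_batch(params, kind, batch, drop_mask)
          loss <- cross_entropy_loss(yb, fw$probs)
          grads <- backward_batch(params, kind, batch, fw, yb, drop_mask)
        }
        if (!is.finite(loss)) {
          abort(paste0("non-finite training loss at epoch ", epoch,
                       " (", kind, "); try a lower learning rate."))
        }
        grads <- clip_grads(grads, config$grad_clip_norm)
        upd <- adam_update(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + loss * B
      }
      train_loss <- epoch_loss / length(ord)
      val_loss <- eval_loss(params, val_idx)
      log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss)
      if (use_val) {
        if (val_loss < best$val - config$min_delta) {
          best <- list(params = params, val = val_loss, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      } else {
        best <- list(params = params, val = train_loss, epoch = epoch)
      }
    }
    final <- if (use_val) best$params else params
    attr(final, "kind") <- a_kind
    structure(list(kind = kind, params = final, config = config,
                   input_dim = input_dim, n_train = length(tr_idx),
                   n_val = length(val_idx), best_epoch = best$epoch,
                   best_val_loss = if (use_val) best$val else NA_real_,
                   log = dplyr::bind_rows(log)),
              class = "phq_model")
  })
}

# Shared prediction core: dropout off, batched.
predict_core <- function(params, kind, x, idx, batch_size = 64L) {
  if (kind == "baseline") {
    return(baseline_forward_cache(params, x[idx, , drop = FALSE])$probs)
  }
  out <- vector("list", ceiling(length(idx) / batch_size))
  chunks <- split(idx, ceiling(seq_along(idx) / batch_size))
  for (j in seq_along(chunks)) {
    batch <- pack_batch(x[chunks[[j]]])
    out[[j]] <- forward_batch(params, kind, batch)$probs
  }
  do.call(rbind, out)
}

#' Predict symptom probabilities
#'
#' Deterministic forward pass (dropout disabled) of a fitted model; rows
#' align with the input order.
#'
#' @param model A fitted `phq_model`.
#' @param x Input in the same form used for training (matrix for the
#'   baseline, list of sequences otherwise).
#' @return N x 9 matrix of probabilities.
#' @export
predict_proba <- function(model, x) {
  if (!inherits(model, "phq_model")) abort("predict_proba requires a fitted phq_model.")
  n <- if (model$kind == "baseline") nrow(x) else length(x)
  probs <- predict_core(model$params, model$kind, x, seq_len(n))
  colnames(probs) <- paste0("S", seq_len(ncol(probs)))
  if (model$kind == "baseline") rownames(probs) <- rownames(x)
  else rownames(probs) <- names(x)
  probs
}

#' Per-token attention weights of a fitted attention model
#'
#' Runs the bidirectional encoder and attention layer over each sequence and
#' returns the normalized attention weights (summing to 1 per post).
#'
#' @param model A fitted `phq_model` with `kind = "bilstm_attention"`.
#' @param x List of token-vector sequences ([post_sequences()]).
#' @return List of numeric weight vectors, one per post.
#' @export
attention_weights <- function(model, x) {
  stopifnot(inherits(model, "phq_model"))
  if (model$kind != "bilstm_attention") {
    abort("attention weights are only defined for kind = 'bilstm_attention'.")
  }
  lapply(x, function(s) {
    fw <- forward_batch(model$params, "bilstm_attention", pack_batch(list(s)))
    drop(fw$att$alpha)[seq_len(nrow(s))]
  })
}

#' @export
print.phq_model <- function(x, ...) {
  cat("<phq_model> ", x$kind, ": input_dim ", x$input_dim,
      ", trained ", nrow(x$log), " epoch(s)",
      if (!is.na(x$best_val_loss)) paste0(", best val loss ",
                                          signif(x$best_val_loss, 4),
                                          " @ epoch ", x$best_epoch),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted model's training log
#'
#' @param x A `phq_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch log tibble (`epoch`, `train_loss`,
#'   `val_loss`). `glance()`: a one-row model summary.
#' @export
tidy.phq_model <- function(x, ...) x$log

#' @rdname tidy.phq_model
#' @export
glance.phq_model <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_parameters = sum(vapply(x$params, length, 1L)),
                 n_train = x$n_train, n_val = x$n_val,
                 epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$log$train_loss[nrow(x$log)])
}
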