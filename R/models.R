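# Forward computations for the four architectures: feedforward baseline,
# LSTM, bidirectional LSTM, and attention pooling. All parameters are plain
# named lists of matrices/vectors so the Adam trainer can treat them
# uniformly.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# Fan-in scaled uniform init, the classic recipe for small recurrent nets.
init_mat <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

#' Initialise model parameters
#'
#' Builds the parameter list for one of the four architectures, with weights
#' drawn uniform scaled by fan-in under the given seed.
#'
#' `baseline`: a feedforward network `input_dim -> 30 -> 20 -> 10 -> 9` with
#' ReLU hidden activations and a 9-unit sigmoid output (one unit per PHQ-9
#' symptom). `lstm`/`bilstm`: recurrent encoders with per-gate input weights
#' `W` (`input_dim x H`) and recurrent weights `U` (`H x H`) for the input,
#' forget, output and candidate gates (no gate biases), mean-pooled over
#' time, followed by a dense sigmoid output layer. `bilstm_attention`:
#' bidirectional encoder whose per-step states are pooled by a learned
#' attention layer instead of the mean.
#'
#' @param kind One of `"baseline"`, `"lstm"`, `"bilstm"`,
#'   `"bilstm_attention"`.
#' @param input_dim Word-vector dimension (the baseline's input is the
#'   mean-pooled post vector of the same dimension).
#' @param hidden_size Recurrent state size H (ignored for the baseline).
#' @param attention_size Attention projection size; default `2 * hidden_size`
#'   (the bidirectional state size).
#' @param n_outputs Number of output units (9 symptoms).
#' @param output_bias Optional length-`n_outputs` initial output bias. The
#'   trainer passes the label base rates on the logit scale, which starts the
#'   network at the marginal prediction instead of 0.5 everywhere and spends
#'   the epoch budget on the discriminative signal.
#' @param seed Integer seed for the initial weights.
#' @return Named list of parameter arrays, with attributes recording the
#'   architecture.
#' @export
init_params <- function(kind = c("baseline", "lstm", "bilstm", "bilstm_attention"),
                        input_dim, hidden_size = 16, attention_size = NULL,
                        n_outputs = 9, output_bias = NULL, seed = 1) {
  kind <- match.arg(kind)
  with_rng(derive_seed(seed, 11L), {
    params <- if (kind == "baseline") {
      list(
        W1 = init_mat(input_dim, 30), b1 = numeric(30),
        W2 = init_mat(30, 20), b2 = numeric(20),
        W3 = init_mat(20, 10), b3 = numeric(10),
        W4 = init_mat(10, n_outputs),
        b4 = output_bias %||% numeric(n_outputs)
      )
    } else {
      H <- hidden_size
      cell <- function(prefix) {
        out <- list()
        for (g in c("i", "f", "o", "c")) {
          out[[paste0(prefix, "W_", g)]] <- init_mat(input_dim, H)
          out[[paste0(prefix, "U_", g)]] <- init_mat(H, H)
        }
        out
      }
      p <- switch(kind,
        lstm = cell("fwd."),
        bilstm = c(cell("fwd."), cell("bwd.")),
        bilstm_attention = c(cell("fwd."), cell("bwd."))
      )
      D <- if (kind == "lstm") H else 2L * H
      if (kind == "bilstm_attention") {
        A <- attention_size %||% D
        p$Wa <- init_mat(D, A)
        p$ba <- numeric(A)
        p$ua <- runif(A, -1, 1) / sqrt(A)
      }
      p$Wo <- init_mat(D, n_outputs)
      p$bo <- output_bias %||% numeric(n_outputs)
      p
    }
    attr(params, "kind") <- kind
    attr(params, "input_dim") <- input_dim
    attr(params, "hidden_size") <- if (kind == "baseline") NA_integer_ else hidden_size
    params
  })
}

#' Feedforward baseline forward pass
#'
#' `h1 = ReLU(x W1 + b1)`, `h2 = ReLU(h1 W2 + b2)`, `h3 = ReLU(h2 W3 + b3)`,
#' `yhat = sigmoid(h3 W4 + b4)`: three ReLU hidden layers (30, 20, 10 units)
#' and a 9-unit sigmoid output, one probability per symptom.
#'
#' @param params Parameter list from [init_params()] (`kind = "baseline"`).
#' @param x Numeric B x input_dim matrix of mean-pooled post embeddings.
#' @return B x 9 matrix of probabilities in (0, 1).
#' @export
feedforward_forward <- function(params, x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("feedforward input must be finite.")
  if (ncol(x) != nrow(params$W1)) {
    abort(paste0("input layer: x has ", ncol(x), " columns but W1 expects ",
                 nrow(params$W1), "."))
  }
  h1 <- relu(sweep(x %*% params$W1, 2, params$b1, `+`))
  h2 <- relu(sweep(h1 %*% params$W2, 2, params$b2, `+`))
  h3 <- relu(sweep(h2 %*% params$W3, 2, params$b3, `+`))
  sigmoid(sweep(h3 %*% params$W4, 2, params$b4, `+`))
}

#' Multi-label binary cross-entropy
#'
#' Mean over the batch of the summed per-symptom binary cross-entropies
#' `-sum_k [y log(yhat) + (1 - y) log(1 - yhat)]`, with probabilities clamped
#' to `[eps, 1 - eps]`.
#'
#' @param y B x K binary matrix of labels.
#' @param y_hat B x K matrix of predicted probabilities.
#' @param eps Clamp, default `1e-7`.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(y, y_hat, eps = 1e-7) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  stopifnot(all(dim(y) == dim(y_hat)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  mean(rowSums(-(y * log(p) + (1 - y) * log(1 - p))))
}

# Pull one direction's gate weights out of the flat parameter list.
gate_params <- function(params, prefix) {
  list(W_i = params[[paste0(prefix, "W_i")]], U_i = params[[paste0(prefix, "U_i")]],
       W_f = params[[paste0(prefix, "W_f")]], U_f = params[[paste0(prefix, "U_f")]],
       W_o = params[[paste0(prefix, "W_o")]], U_o = params[[paste0(prefix, "U_o")]],
       W_c = params[[paste0(prefix, "W_c")]], U_c = params[[paste0(prefix, "U_c")]])
}

#' One LSTM step
#'
#' The gate equations of the recurrent cell, applied to a batch (rows) or a
#' single input vector:
#' `i_t = sigmoid(x_t W_i + h_prev U_i)`, `f_t = sigmoid(x_t W_f + h_prev U_f)`,
#' `o_t = sigmoid(x_t W_o + h_prev U_o)`, `c~_t = tanh(x_t W_c + h_prev U_c)`,
#' `c_t = f_t * c_prev + i_t * c~_t`, `h_t = o_t * tanh(c_t)`.
#'
#' @param params List with `W_i`, `U_i`, `W_f`, `U_f`, `W_o`, `U_o`, `W_c`,
#'   `U_c` (e.g. the `fwd.`-prefixed block of [init_params()] output).
#' @param x_t Input vector (length input_dim) or B x input_dim matrix.
#' @param h_prev,c_prev Previous hidden/cell state, vector of length H or
#'   B x H matrix.
#' @return List with elements `h`, `c` (and the gate activations `i`, `f`,
#'   `o`, `g` for inspection).
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  vec_in <- is.null(dim(x_t))
  x <- if (vec_in) matrix(x_t, 1) else as.matrix(x_t)
  h <- if (is.null(dim(h_prev))) matrix(h_prev, 1) else as.matrix(h_prev)
  c_ <- if (is.null(dim(c_prev))) matrix(c_prev, 1) else as.matrix(c_prev)
  if (!all(is.finite(x), is.finite(h), is.finite(c_))) {
    abort("lstm_step requires finite inputs.")
  }
  i <- sigmoid(x %*% params$W_i + h %*% params$U_i)
  f <- sigmoid(x %*% params$W_f + h %*% params$U_f)
  o <- sigmoid(x %*% params$W_o + h %*% params$U_o)
  g <- tanh(x %*% params$W_c + h %*% params$U_c)
  c_t <- f * c_ + i * g
  h_t <- o * tanh(c_t)
  if (vec_in) {
    list(h = drop(h_t), c = drop(c_t), i = drop(i), f = drop(f), o = drop(o), g = drop(g))
  } else {
    list(h = h_t, c = c_t, i = i, f = f, o = o, g = g)
  }
}

#' Encode a token-vector sequence
#'
#' Runs the recurrent encoder over one sequence. For `"lstm"` the per-step
#' states are the forward hidden states; for `"bilstm"` the backward pass
#' reads the sequence from its end and each step's state is the
#' concatenation of the forward and backward hidden states (size 2H). The
#' pooled state is the element-wise mean over timesteps (the attention
#' variant replaces this pooling; see [attention_pool()]).
#'
#' @param kind `"lstm"` or `"bilstm"`.
#' @param params Parameter list from [init_params()] of the matching kind.
#' @param x T x input_dim matrix: one row per token, in reading order.
#' @return List with `states` (T x H or T x 2H) and `pooled` (mean over
#'   rows).
#' @export
encode_sequence <- function(kind = c("lstm", "bilstm"), params, x) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("cannot encode an empty sequence.")
  H <- ncol(params[["fwd.U_i"]])
  run_dir <- function(prefix, xs) {
    p <- gate_params(params, prefix)
    h <- numeric(H); c_ <- numeric(H)
    out <- matrix(0, nrow(xs), H)
    for (t in seq_len(nrow(xs))) {
      st <- lstm_step(p, xs[t, ], h, c_)
      h <- st$h; c_ <- st$c
      out[t, ] <- h
    }
    out
  }
  fwd <- run_dir("fwd.", x)
  states <- if (kind == "lstm") {
    fwd
  } else {
    bwd <- run_dir("bwd.", x[rev(seq_len(nrow(x))), , drop = FALSE])
    cbind(fwd, bwd[rev(seq_len(nrow(x))), , drop = FALSE])
  }
  list(states = states, pooled = colMeans(states))
}

#' Attention pooling over per-step states
#'
#' `v_t = tanh(h_t Wa + ba)`, `s_t = v_t . ua`,
#' `alpha = softmax(s)`, `pooled = sum_t alpha_t h_t`. The weights are a
#' convex combination (positive, summing to 1) and double as the per-token
#' importance used for visualisation.
#'
#' @param params List with `Wa` (D x A), `ba` (A), `ua` (A).
#' @param states T x D matrix of per-step states.
#' @return List with `pooled` (length D) and `weights` (length T).
#' @export
attention_pool <- function(params, states) {
  states <- as.matrix(states)
  if (nrow(states) == 0) abort("attention_pool needs at least one state.")
  v <- tanh(sweep(states %*% params$Wa, 2, params$ba, `+`))
  s <- drop(v %*% params$ua)
  s <- s - max(s)
  alpha <- exp(s) / sum(exp(s))
  list(pooled = drop(crossprod(alpha, states)), weights = alpha)
}

#' Multi-label predictive entropy
#'
#' Uncertainty of a multi-label sigmoid prediction: the sum over symptoms of
#' the binary entropy `-p log p - (1-p) log(1-p)` in nats, with
#' `0 log 0 := 0`. Maximal (`9 log 2`) when every probability is 0.5, zero
#' when all are 0 or 1.
#'
#' @param probs Numeric vector of probabilities, or an N x K matrix (one row
#'   per instance).
#' @return Scalar entropy, or a vector of length N for matrix input.
#' @export
multilabel_entropy <- function(probs) {
  p <- as.matrix(probs)
  if (is.null(dim(probs))) p <- matrix(probs, 1)
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1].")
  h <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log(q) - (1 - q) * log(1 - q))
  out <- rowSums(h(p))
  if (is.null(dim(probs))) out[1] else out
}
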