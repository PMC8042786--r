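# Forward passes are checked against independent brute-force oracles, and
# the analytic gradients against numerical differentiation.

test_that("feedforward forward pass matches a layer-by-layer oracle", {
  set.seed(11)
  params <- init_params("baseline", input_dim = 7, seed = 11)
  x <- matrix(rnorm(4 * 7), 4, 7)
  probs <- feedforward_forward(params, x)
  expect_true(all(probs > 0 & probs < 1))

  # scalar-loop oracle, written independently of the matrix implementation
  oracle_row <- function(xi) {
    lay <- function(v, W, b, act) {
      out <- numeric(ncol(W))
      for (j in seq_len(ncol(W))) {
        s <- b[j]
        for (d in seq_along(v)) s <- s + v[d] * W[d, j]
        out[j] <- act(s)
      }
      out
    }
    h <- lay(xi, params$W1, params$b1, function(z) max(z, 0))
    h <- lay(h, params$W2, params$b2, function(z) max(z, 0))
    h <- lay(h, params$W3, params$b3, function(z) max(z, 0))
    lay(h, params$W4, params$b4, function(z) 1 / (1 + exp(-z)))
  }
  for (i in 1:4) {
    expect_equal(unname(probs[i, ]), oracle_row(x[i, ]), tolerance = 1e-6)
  }

  # all-zero parameters give sigmoid(0) = 0.5 everywhere
  zero <- lapply(params, function(p) p * 0)
  expect_equal(unname(feedforward_forward(zero, x)),
               matrix(0.5, 4, 9), ignore_attr = TRUE)
  # duplicated rows give identical outputs
  x2 <- rbind(x[1, ], x[1, ])
  p2 <- feedforward_forward(params, x2)
  expect_equal(p2[1, ], p2[2, ])
  expect_error(feedforward_forward(params, matrix(1, 2, 3)), "W1")
})

test_that("cross-entropy matches closed forms and a scalar oracle", {
  y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 0, 0), 1, 9)
  expect_lt(cross_entropy_loss(y, y), 9 * 1e-6)
  half <- matrix(0.5, 1, 9)
  expect_equal(cross_entropy_loss(y, half), 9 * log(2), tolerance = 1e-12)

  set.seed(12)
  yh <- matrix(runif(9, 0.05, 0.95), 1, 9)
  oracle <- 0
  for (k in 1:9) {
    oracle <- oracle - (y[k] * log(yh[k]) + (1 - y[k]) * log(1 - yh[k]))
  }
  expect_equal(cross_entropy_loss(y, yh), oracle, tolerance = 1e-12)
})

test_that("lstm_step follows the gate equations exactly", {
  H <- 3; d <- 4
  p <- init_params("lstm", d, hidden_size = H, seed = 2)
  gates <- phqminer:::gate_params(p, "fwd.")
  zero <- lapply(gates, function(w) w * 0)

  st <- lstm_step(zero, rnorm(d), numeric(H), numeric(H))
  expect_equal(st$h, numeric(H))
  c_prev <- c(1, -2, 0.5)
  st2 <- lstm_step(zero, rnorm(d), numeric(H), c_prev)
  expect_equal(st2$c, 0.5 * c_prev)  # f = sigmoid(0) = 0.5, i*g = 0

  # element-wise oracle of the six equations
  set.seed(2)
  x <- rnorm(d); h0 <- rnorm(H); c0 <- rnorm(H)
  st3 <- lstm_step(gates, x, h0, c0)
  sig <- function(z) 1 / (1 + exp(-z))
  for (j in seq_len(H)) {
    i_j <- sig(sum(x * gates$W_i[, j]) + sum(h0 * gates$U_i[, j]))
    f_j <- sig(sum(x * gates$W_f[, j]) + sum(h0 * gates$U_f[, j]))
    o_j <- sig(sum(x * gates$W_o[, j]) + sum(h0 * gates$U_o[, j]))
    g_j <- tanh(sum(x * gates$W_c[, j]) + sum(h0 * gates$U_c[, j]))
    c_j <- f_j * c0[j] + i_j * g_j
    expect_equal(st3$c[j], c_j, tolerance = 1e-6)
    expect_equal(st3$h[j], o_j * tanh(c_j), tolerance = 1e-6)
  }
})

test_that("sequence encoding pools states as documented", {
  d <- 4; H <- 3
  p1 <- init_params("lstm", d, hidden_size = H, seed = 3)
  x1 <- matrix(rnorm(d), 1, d)
  enc1 <- encode_sequence("lstm", p1, x1)
  expect_equal(enc1$pooled, drop(enc1$states))

  # mean pooling equals the oracle average of per-step states
  xs <- matrix(rnorm(5 * d), 5, d)
  enc <- encode_sequence("lstm", p1, xs)
  expect_equal(enc$pooled, colMeans(enc$states), tolerance = 1e-12)

  # bilstm with tied directions on a palindromic sequence is symmetric
  p2 <- init_params("bilstm", d, hidden_size = H, seed = 4)
  for (g in c("i", "f", "o", "c")) {
    p2[[paste0("bwd.W_", g)]] <- p2[[paste0("fwd.W_", g)]]
    p2[[paste0("bwd.U_", g)]] <- p2[[paste0("fwd.U_", g)]]
  }
  pal <- rbind(xs, xs[rev(seq_len(nrow(xs) - 1)), ])
  encp <- encode_sequence("bilstm", p2, pal)
  T_ <- nrow(pal)
  for (t in seq_len(T_)) {
    expect_equal(encp$states[t, 1:H], encp$states[T_ + 1 - t, H + 1:H],
                 tolerance = 1e-12)
  }
  expect_error(encode_sequence("lstm", p1, matrix(0, 0, d)), "empty")
})

test_that("attention pooling is a softmax-weighted convex combination", {
  D <- 6
  p <- init_params("bilstm_attention", 4, hidden_size = 3, seed = 5)
  one <- matrix(rnorm(D), 1, D)
  a1 <- attention_pool(p, one)
  expect_equal(a1$weights, 1)
  expect_equal(a1$pooled, drop(one))

  same <- matrix(rep(rnorm(D), 4), 4, byrow = TRUE)
  a2 <- attention_pool(p, same)
  expect_equal(a2$weights, rep(0.25, 4))

  # two-line softmax / weighted-sum oracle
  set.seed(5)
  states <- matrix(rnorm(5 * D), 5, D)
  a3 <- attention_pool(p, states)
  v <- tanh(sweep(states %*% p$Wa, 2, p$ba, `+`))
  s <- drop(v %*% p$ua)
  w_oracle <- exp(s) / sum(exp(s))
  expect_equal(a3$weights, w_oracle, tolerance = 1e-6)
  expect_equal(a3$pooled, drop(t(states) %*% w_oracle), tolerance = 1e-6)
  expect_equal(sum(a3$weights), 1, tolerance = 1e-12)
  expect_true(all(a3$weights > 0))
})

test_that("analytic gradients agree with numerical differentiation", {
  num_grad <- function(fn, params, eps = 1e-5) {
    lapply(params, function(p) {
      g <- p * 0
      for (k in seq_along(p)) {
        p1 <- p; p1[k] <- p1[k] + eps
        p2 <- p; p2[k] <- p2[k] - eps
        g[k] <- (fn(p1, k) - fn(p2, k)) / (2 * eps)
      }
      g
    })
  }
  set.seed(21)
  B <- 3; d <- 3; H <- 2
  seqs <- lapply(c(3, 1, 2), function(T_) matrix(rnorm(T_ * d), T_, d))
  y <- matrix(rbinom(B * 9, 1, 0.5), B, 9)
  for (kind in c("lstm", "bilstm", "bilstm_attention")) {
    params <- init_params(kind, d, hidden_size = H, seed = 21)
    pk <- phqminer:::pack_batch(seqs)
    fw <- phqminer:::forward_batch(params, kind, pk)
    an <- phqminer:::backward_batch(params, kind, pk, fw, y)
    for (nm in names(an)) {
      fn <- function(pval, k) {
        pp <- params
        pp[[nm]][k] <- pval[k]
        cross_entropy_loss(y, phqminer:::forward_batch(pp, kind, pk)$probs)
      }
      nu <- num_grad(fn, params[nm])[[nm]]
      expect_lt(max(abs(as.matrix(an[[nm]]) - as.matrix(nu))), 1e-6,
                label = paste(kind, nm, "max abs gradient difference"))
    }
  }
})

test_that("training reduces loss on a learnable task and is reproducible", {
  set.seed(31)
  n <- 60
  x <- matrix(rnorm(n * 6, sd = 0.5), n, 6)
  y <- matrix(0L, n, 9)
  y[, 1] <- as.integer(x[, 1] > 0)
  y[, 2] <- as.integer(x[, 2] > 0)
  rownames(x) <- sprintf("p%02d", 1:n)

  cfg <- train_config(max_epochs = 40, batch_size = 8, val_fraction = 0,
                      seed = 7)
  m1 <- train_model(x, y, "baseline", cfg)
  expect_lte(tail(m1$log$train_loss, 1), m1$log$train_loss[1])

  m2 <- train_model(x, y, "baseline", cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)

  p1 <- predict_proba(m1, x)
  expect_identical(p1, predict_proba(m1, x))
  expect_true(all(p1 > 0 & p1 < 1))
  # single-post prediction equals the matching batch row
  expect_equal(predict_proba(m1, x[3, , drop = FALSE])[1, ], p1[3, ])
})

test_that("early stopping halts once validation stalls and keeps the best", {
  set.seed(32)
  n <- 50
  x <- matrix(rnorm(n * 4), n, 4)
  y <- matrix(rbinom(n * 9, 1, 0.5), n, 9)  # pure noise: validation cannot improve long
  cfg <- train_config(max_epochs = 200, batch_size = 8, patience = 3,
                      val_fraction = 0.3, seed = 9)
  m <- train_model(x, y, "baseline", cfg)
  expect_lt(nrow(m$log), 200)
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  tail_vals <- m$log$val_loss[seq(m$best_epoch + 1, nrow(m$log))]
  expect_equal(length(tail_vals), 3)  # stopped exactly `patience` epochs later
})

test_that("a separable token task is learned by the recurrent models", {
  set.seed(33)
  vt <- fixed_vector_table(list(
    bad = c(1, 0, 0, 0), good = c(0, 1, 0, 0),
    blah = c(0, 0, 1, 0), meh = c(0, 0, 0, 1)
  ))
  n <- 40
  words <- lapply(1:n, function(i) {
    base <- sample(c("blah", "meh"), 4, TRUE)
    if (i %% 2 == 0) base[sample(4, 1)] <- "bad"
    base
  })
  seqs <- lapply(words, function(w) vt$vectors[w, , drop = FALSE])
  names(seqs) <- sprintf("p%02d", 1:n)
  y <- matrix(0L, n, 9)
  y[, 1] <- as.integer(vapply(words, function(w) "bad" %in% w, TRUE))

  cfg <- train_config(max_epochs = 200, batch_size = 4, val_fraction = 0,
                      dropout = 0, hidden_size = 4, seed = 3)
  m <- train_model(seqs, y, "bilstm_attention", cfg)
  expect_lt(tail(m$log$train_loss, 1), 0.1)
  p <- predict_proba(m, seqs)
  expect_equal(roc_auc(p[, 1], y[, 1]), 1.0)
})

test_that("multi-label entropy has the documented extremes and symmetry", {
  expect_equal(multilabel_entropy(rep(0.5, 9)), 9 * log(2))
  expect_equal(multilabel_entropy(c(0, 1, 0, 1, 1, 0, 0, 0, 1)), 0)
  p <- c(0.9, 0.5, rep(0, 7))
  expect_equal(multilabel_entropy(p),
               binary_entropy(0.9) + binary_entropy(0.5), tolerance = 1e-6)
  expect_equal(multilabel_entropy(p), multilabel_entropy(1 - p))
  m <- rbind(rep(0.5, 9), rep(0.01, 9))
  out <- multilabel_entropy(m)
  expect_length(out, 2)
  expect_true(out[1] > out[2])
  expect_error(multilabel_entropy(c(1.2, rep(0.5, 8))), "\\[0, 1\\]")
})

test_that("the batched compiled path matches the reference sequence encoder", {
  set.seed(77)
  p <- init_params("bilstm_attention", 5, hidden_size = 3, seed = 77)
  s <- matrix(rnorm(6 * 5), 6, 5)
  enc <- encode_sequence("bilstm", p, s)
  ap <- attention_pool(p, enc$states)
  fw <- phqminer:::forward_batch(p, "bilstm_attention",
                                 phqminer:::pack_batch(list(s)))
  expect_equal(drop(fw$att$alpha), ap$weights, tolerance = 1e-10)
  expect_equal(drop(fw$pooled), ap$pooled, tolerance = 1e-10)
  expect_equal(attention_weights(
    structure(list(kind = "bilstm_attention", params = p), class = "phq_model"),
    list(a = s))$a, ap$weights, tolerance = 1e-10)
})
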