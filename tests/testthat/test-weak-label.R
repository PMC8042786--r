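test_that("cosine similarity matches closed forms and handles zero norms", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0, 0), c(1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(NA, 1), c(1, 1)), "finite")
  expect_error(cosine_similarity(c(Inf, 1), c(1, 1)), "finite")
})

test_that("similarity profiles peak at the planted symptom under orthogonal clusters", {
  lex <- seeds_only_lexicon()
  vt <- generate_vector_fixture(lex, dim = 16, cohesion = Inf, seed = 2)
  posts <- tibble::tibble(post_id = "p1", text = "dead suicide dead")
  corpus <- preprocess_corpus(posts)
  prof <- similarity_profiles(corpus, lex, vt)
  scores <- as.numeric(prof[1, paste0("S", 1:9)])
  expect_equal(which.max(scores), 9)
  expect_true(all(scores >= 0 & scores <= 1))

  # an empty post yields an all-zero profile with a warning
  empty <- preprocess_corpus(tibble::tibble(post_id = "e", text = ""))
  expect_warning(p0 <- similarity_profiles(empty, lex, vt), "all-zero")
  expect_equal(as.numeric(p0[1, paste0("S", 1:9)]), rep(0, 9))
})

test_that("similarity profiles are invariant to token order", {
  lex <- test_lexicon(top_k = 2)
  vt <- generate_vector_fixture(lex, dim = 16, seed = 3)
  a <- preprocess_corpus(tibble::tibble(post_id = "x", text = "dead tired sleep energy"))
  b <- preprocess_corpus(tibble::tibble(post_id = "x", text = "energy sleep tired dead"))
  pa <- similarity_profiles(a, lex, vt)
  pb <- similarity_profiles(b, lex, vt)
  expect_equal(pa[, paste0("S", 1:9)], pb[, paste0("S", 1:9)])
})

test_that("binarization applies thresholds with boundary semantics", {
  prof <- tibble::tibble(post_id = c("a", "b"))
  sc <- seq(0.05, 0.85, length.out = 9)
  for (k in 1:9) prof[[paste0("S", k)]] <- c(sc[k], 1 - sc[k])
  all1 <- binarize(prof, 0)
  expect_true(all(label_matrix_values(all1) == 1L))
  all0 <- binarize(prof, 1)
  expect_true(all(label_matrix_values(all0) == 0L))
  half <- binarize(prof, 0.5)
  expect_equal(as.integer(half[1, paste0("S", 1:9)]), as.integer(sc >= 0.5))
  # per-symptom thresholds and monotonicity in the threshold
  for (k in 1:9) {
    lo <- binarize(prof, rep(0.2, 9))
    hi <- binarize(prof, rep(0.8, 9))
    expect_lte(sum(label_matrix_values(hi)[, k]), sum(label_matrix_values(lo)[, k]))
  }
  expect_error(binarize(prof, c(0.5, 0.5)), "length-9")
  expect_error(binarize(prof, 1.5), "\\[0, 1\\]")
})

test_that("threshold calibration recovers a separating threshold (Youden's J)", {
  set.seed(5)
  n <- 60
  prof <- tibble::tibble(post_id = sprintf("p%02d", 1:n))
  gold <- tibble::tibble(post_id = prof$post_id)
  t_star <- seq(0.2, 0.6, length.out = 9)
  for (k in 1:9) {
    s <- runif(n)
    prof[[paste0("S", k)]] <- s
    gold[[paste0("S", k)]] <- as.integer(s >= t_star[k])
  }
  # force both classes everywhere
  for (k in 1:9) gold[[paste0("S", k)]][1:2] <- c(0L, 1L)
  prof_adj <- prof
  for (k in 1:9) {
    prof_adj[[paste0("S", k)]][1:2] <- c(t_star[k] - 0.01, t_star[k] + 0.01)
  }
  thr <- calibrate_thresholds(prof_adj, gold)
  relab <- binarize(prof_adj, thr$threshold)
  expect_equal(label_matrix_values(relab), label_matrix_values(gold))
  expect_true(all(thr$youden_j == 1))
  expect_true(all(thr$threshold <= t_star + 0.011))
})

test_that("single-class gold labels fall back to threshold 0.5 with a warning", {
  prof <- tibble::tibble(post_id = c("a", "b", "c"))
  gold <- tibble::tibble(post_id = c("a", "b", "c"))
  for (k in 1:9) {
    prof[[paste0("S", k)]] <- c(0.1, 0.5, 0.9)
    gold[[paste0("S", k)]] <- if (k == 1) c(0L, 0L, 0L) else c(0L, 1L, 1L)
  }
  expect_warning(thr <- calibrate_thresholds(prof, gold), "S1")
  expect_equal(thr$threshold[1], 0.5)
  expect_true(all(thr$threshold[-1] <= 0.5))
})

test_that("planted-symptom ranking beats chance strongly on a small corpus", {
  lex <- test_lexicon()
  vt <- generate_vector_fixture(lex, dim = 300, seed = 6)
  spec <- synthetic_spec(n_posts = 150, seed = 6)
  corp <- generate_corpus(spec, lex)
  res <- weak_label_corpus(corp$posts, lex, vt)
  truth <- label_matrix_values(corp$truth)
  for (k in 1:9) {
    expect_gt(roc_auc(res$profiles[[paste0("S", k)]], truth[, k]), 0.9)
  }
})
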