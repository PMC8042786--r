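test_that("corpus generation honours size, prevalence and planting", {
  lex <- seeds_only_lexicon()
  empty <- generate_corpus(synthetic_spec(n_posts = 0), lex)
  expect_equal(nrow(empty$posts), 0)
  expect_equal(nrow(empty$truth), 0)

  spec <- synthetic_spec(n_posts = 40, prevalence = c(0, 0, 1, rep(0, 6)),
                         signal = 4, mean_words = 60, seed = 5)
  corp <- generate_corpus(spec, lex)
  truth <- label_matrix_values(corp$truth)
  expect_true(all(truth[, 3] == 1))
  expect_true(all(truth[, -3] == 0))
  s3_terms <- lex$term[lex$symptom_id == "S3"]
  hits <- vapply(corp$posts$text, function(tx) {
    any(s3_terms %in% tokenize(normalize_text(tx)))
  }, TRUE)
  expect_true(all(hits))
  expect_true(all(lengths(corp$posts$planted) >= 1))
})

test_that("generation is byte-identical under a fixed seed", {
  lex <- test_lexicon()
  spec <- synthetic_spec(n_posts = 25, seed = 77)
  a <- generate_corpus(spec, lex)
  b <- generate_corpus(spec, lex)
  expect_identical(a$posts, b$posts)
  expect_identical(a$truth, b$truth)
  c_ <- generate_corpus(synthetic_spec(n_posts = 25, seed = 78), lex)
  expect_false(identical(a$posts$text, c_$posts$text))
})

test_that("label marginals converge to the prevalence", {
  lex <- seeds_only_lexicon()
  spec <- synthetic_spec(n_posts = 1200, prevalence = 0.3, mean_words = 40,
                         seed = 9)
  corp <- generate_corpus(spec, lex)
  rates <- colMeans(label_matrix_values(corp$truth))
  # three-sigma binomial band around 0.3 at n = 1200
  band <- 3 * sqrt(0.3 * 0.7 / 1200)
  expect_true(all(abs(rates - 0.3) < band))
})

test_that("generated corpora round-trip through JSONL losslessly", {
  lex <- test_lexicon()
  corp <- generate_corpus(synthetic_spec(n_posts = 12, seed = 3), lex)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(dplyr::select(corp$posts, "post_id", "text"), path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$post_id, corp$posts$post_id)
  expect_equal(back$text, corp$posts$text)
})

test_that("post lengths match the corpus statistics being emulated", {
  lex <- seeds_only_lexicon()
  corp <- generate_corpus(synthetic_spec(n_posts = 150, seed = 12), lex)
  corpus <- preprocess_corpus(corp$posts)
  words <- mean(lengths(corpus$tokens))
  expect_gt(words, 200)
  expect_lt(words, 265)
  expect_gt(mean(corpus$n_sentences), 7)
  expect_lt(mean(corpus$n_sentences), 11)
})

test_that("vector fixtures cluster lexicon terms around orthogonal anchors", {
  lex <- test_lexicon()
  # infinite cohesion collapses each symptom onto its anchor
  vt_inf <- generate_vector_fixture(lex, dim = 16, cohesion = Inf, seed = 2,
                                    extra_words = "filler")
  s9 <- lex$term[lex$symptom_id == "S9"]
  base <- vt_inf$vectors[s9[1], ]
  for (tm in s9[-1]) expect_equal(unname(vt_inf$vectors[tm, ]), unname(base))
  # distinct symptoms are exactly orthogonal in the limit
  s1 <- lex$term[lex$symptom_id == "S1"][1]
  expect_equal(cosine_similarity(vt_inf$vectors[s1, ], base), 0,
               tolerance = 1e-10)

  # finite cohesion: within-symptom cosines exceed cross-symptom cosines
  vt <- generate_vector_fixture(lex, dim = 32, cohesion = 2, seed = 2)
  within <- c()
  across <- c()
  for (k in c(2, 5, 9)) {
    terms <- lex$term[lex$symptom_id == paste0("S", k)]
    within <- c(within, cosine_similarity(vt$vectors[terms[1], ],
                                          vt$vectors[terms[2], ]))
    other <- lex$term[lex$symptom_id == paste0("S", (k %% 9) + 1)][1]
    across <- c(across, cosine_similarity(vt$vectors[terms[1], ],
                                          vt$vectors[other, ]))
  }
  expect_gt(mean(within), mean(across))
  expect_error(generate_vector_fixture(lex, dim = 5), "dim >= 9")
})

test_that("the miniature lexical database expands every seed consistently", {
  seeds <- read_seed_lexicon()
  db <- mini_lexical_db(seeds, seed = 1)
  expect_equal(lexdb_lookup(db, "banal-filler-word", "synonym"), character(0))
  for (i in 1:9) {
    for (s in seeds$seeds[[i]]) {
      expect_gte(length(lexdb_lookup(db, s, "synonym")), 2)
      expect_length(lexdb_lookup(db, s, "hypernym"), 1)
    }
  }
  # derived names carry the symptom through expansion into the fixture
  lex <- expand_lexicon(seeds, db)
  syn <- lex[lex$provenance == "synonym", ]
  expect_gt(nrow(syn), 18)
  expect_true(all(grepl("_syn", syn$term)))
})

test_that("weak-label difficulty falls as the planted signal weakens", {
  lex <- test_lexicon()
  auc_at_signal <- function(s, sd) {
    spec <- synthetic_spec(n_posts = 250, signal = s, seed = 300 + sd)
    corp <- generate_corpus(spec, lex)
    vt <- generate_vector_fixture(lex, dim = 300, seed = 300 + sd)
    res <- weak_label_corpus(corp$posts, lex, vt)
    truth <- label_matrix_values(corp$truth)
    mean(vapply(1:9, function(k) {
      roc_auc(res$profiles[[paste0("S", k)]], truth[, k])
    }, 0))
  }
  grid <- c(0.25, 1, 3)
  means <- vapply(grid, function(s) {
    mean(vapply(1:5, function(sd) auc_at_signal(s, sd), 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1])
})

test_that("the label-correlation knob induces positive label dependence", {
  lex <- seeds_only_lexicon()
  spec0 <- synthetic_spec(n_posts = 800, mean_words = 30, seed = 21,
                          label_correlation = 0)
  spec1 <- synthetic_spec(n_posts = 800, mean_words = 30, seed = 21,
                          label_correlation = 0.7)
  y0 <- label_matrix_values(generate_corpus(spec0, lex)$truth)
  y1 <- label_matrix_values(generate_corpus(spec1, lex)$truth)
  c0 <- mean(cor(y0)[upper.tri(diag(9))])
  c1 <- mean(cor(y1)[upper.tri(diag(9))])
  expect_gt(c1, c0 + 0.2)
  expect_true(all(abs(colMeans(y1) - 0.3) < 3 * sqrt(0.3 * 0.7 / 800) + 0.02))
})
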