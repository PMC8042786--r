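test_that("both word-vector text dialects load with auto-detection", {
  glove <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sad 0.1 0.2 0.3", "glad 1 0 -1"), glove)
  vt <- read_word_vectors(glove)
  expect_equal(nrow(vt$vectors), 2)
  expect_equal(vt$dim, 3)
  expect_equal(unname(vt$vectors["sad", ]), c(0.1, 0.2, 0.3))

  w2v <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("5 4", paste("w", 1:5, " ", t(replicate(5, 1:4)) |>
                              apply(1, paste, collapse = " "), sep = "")), w2v)
  vt2 <- read_word_vectors(w2v)
  expect_equal(nrow(vt2$vectors), 5)
  expect_equal(vt2$dim, 4)
})

test_that("word-vector format errors are located and duplicates deduplicated", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sad 0.1 0.2 0.3", "glad 1 0"), bad)
  expect_error(read_word_vectors(bad), "line 2")
  good <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sad 0.1 0.2 0.3", "glad 1 0 1"), good)
  expect_error(read_word_vectors(good, expected_dim = 5), "expected_dim")
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("sad 1 2 3", "sad 4 5 6"), dup)
  expect_warning(vt <- read_word_vectors(dup), "duplicated")
  expect_equal(unname(vt$vectors["sad", ]), c(1, 2, 3))
})

test_that("word-vector tables round-trip through write/read to 1e-6", {
  set.seed(7)
  vt <- word_vector_table(matrix(rnorm(40), 8, 5), paste0("w", 1:8))
  path <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(vt, path)
  back <- read_word_vectors(path)
  expect_equal(back$vectors, vt$vectors, tolerance = 1e-6)
})

test_that("the emotion vocabulary is the union of content words and expansions", {
  empty <- preprocess_corpus(tibble::tibble(post_id = "e", text = ""))
  expect_equal(nrow(build_emotion_vocabulary(empty, toy_lexdb())), 0)

  one <- preprocess_corpus(tibble::tibble(post_id = "p", text = "sad"))
  vocab <- build_emotion_vocabulary(one, lexdb(list(sad = list(synonym = "unhappy"))))
  expect_setequal(vocab$word, c("sad", "unhappy"))
  expect_equal(vocab$source[vocab$word == "unhappy"], "lexical-expansion")

  posts <- preprocess_corpus(tibble::tibble(
    post_id = c("a", "b"),
    text = c("i cannot sleep tonight", "dead tired again")
  ))
  vocab2 <- build_emotion_vocabulary(posts, toy_lexdb())
  content <- unique(unlist(posts$content_tokens))
  expect_true(all(content %in% vocab2$word))
})

test_that("domain embedding: PPMI floor, symmetry, determinism, clustering", {
  counts <- phqminer:::cooccurrence_counts(
    list(c("a", "b", "a"), c("b", "c")), c("a", "b", "c"), window = 2)
  expect_true(isSymmetric(counts))
  ppmi <- phqminer:::ppmi_transform(counts)
  expect_equal(ppmi["a", "c"], 0)  # never co-occur
  expect_true(all(ppmi >= 0))

  # two closed co-occurrence clusters separate in the learned space
  grp_a <- c("ash", "alder", "aspen")
  grp_b <- c("bass", "bream", "barbel")
  set.seed(3)
  docs <- c(replicate(30, paste(sample(grp_a, 5, TRUE), collapse = " ")),
            replicate(30, paste(sample(grp_b, 5, TRUE), collapse = " ")))
  corpus <- preprocess_corpus(tibble::tibble(post_id = as.character(1:60), text = docs))
  vt <- train_domain_embedding(corpus, dim = 3)
  cos <- function(a, b) cosine_similarity(vt$vectors[a, ], vt$vectors[b, ])
  within <- mean(c(cos("ash", "alder"), cos("alder", "aspen"),
                   cos("bass", "bream"), cos("bream", "barbel")))
  across <- mean(c(cos("ash", "bass"), cos("alder", "bream"), cos("aspen", "barbel")))
  expect_gt(within, across)

  vt2 <- train_domain_embedding(corpus, dim = 3)
  expect_identical(vt$vectors, vt2$vectors)
  expect_error(train_domain_embedding(corpus, dim = 1000), "vocabulary size")
})

test_that("token embedding is the mean of in-vocabulary vectors", {
  vt <- fixed_vector_table(list(a = c(1, 0), b = c(0, 1)))
  expect_equal(as.numeric(embed_tokens("a", vt)), c(1, 0))
  expect_equal(as.numeric(embed_tokens(c("a", "b"), vt)), c(0.5, 0.5))
  oov <- embed_tokens(c("x", "y"), vt)
  expect_equal(as.numeric(oov), c(0, 0))
  expect_equal(attr(oov, "n_oov"), 2)
  # permutation invariance
  toks <- c("a", "b", "a", "b", "b")
  expect_equal(as.numeric(embed_tokens(toks, vt)),
               as.numeric(embed_tokens(rev(toks), vt)))
})
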