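test_that("bundled seed lexicon loads all nine symptoms with normalized seeds", {
  seeds <- read_seed_lexicon()
  expect_equal(nrow(seeds), 9)
  expect_equal(seeds$symptom_id, paste0("S", 1:9))
  expect_setequal(seeds$seeds[[9]], c("dead", "hurt", "suicide"))
  expect_setequal(seeds$seeds[[5]], c("appetite", "overeating"))
  expect_true(all(vapply(seeds$seeds, function(s) all(s == tolower(s)), TRUE)))
  expect_true(all(vapply(seeds$seeds, function(s) !any(grepl("\\s", s)), TRUE)))
})

test_that("malformed seed lexicon files are rejected with the offending row", {
  full <- readLines(system.file("extdata", "phq9_seed_lexicon.tsv",
                                package = "phqminer"))
  f8 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(full[1:8], f8)
  expect_error(read_seed_lexicon(f8), "S9")

  fdup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(full, full[1]), fdup)
  expect_error(read_seed_lexicon(fdup), "duplicated")

  fextra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(full, "S10\textra\tfoo"), fextra)
  expect_error(read_seed_lexicon(fextra), "S10")

  fragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(full[1:8], "S9\tonly-two-fields"), fragged)
  expect_error(read_seed_lexicon(fragged), "row 9")
})

test_that("expansion through an empty database is the identity on seeds", {
  lex <- expand_lexicon(read_seed_lexicon(), lexdb())
  expect_equal(unique(lex$provenance), "seed")
  s9 <- lex[lex$symptom_id == "S9", ]
  expect_equal(s9$term, c("dead", "hurt", "suicide"))
})

test_that("expansion truncates to top_k per relation and skips duplicates", {
  seeds <- read_seed_lexicon()
  lex <- expand_lexicon(seeds, toy_lexdb(), top_k = 2)
  s3 <- lex[lex$symptom_id == "S3", ]
  expect_true(all(c("slumber", "nap") %in% s3$term))
  expect_false("rest" %in% s3$term)
  expect_equal(s3$provenance[match(c("slumber", "nap"), s3$term)],
               c("synonym", "synonym"))
  # a seed appearing in its own expansion list is not duplicated
  db_self <- lexdb(list(dead = list(synonym = c("dead", "deceased"))))
  lex2 <- expand_lexicon(seeds, db_self, top_k = 5)
  s9 <- lex2[lex2$symptom_id == "S9", ]
  expect_equal(sum(s9$term == "dead"), 1)
  expect_true("deceased" %in% s9$term)
})

test_that("expansion is monotone in top_k and top_k = 0 returns seeds", {
  seeds <- read_seed_lexicon()
  db <- mini_lexical_db(seeds, seed = 4)
  lex0 <- expand_lexicon(seeds, db, top_k = 0)
  expect_equal(lex0$term, unlist(seeds$seeds))
  for (k in 0:4) {
    a <- expand_lexicon(seeds, db, top_k = k)
    b <- expand_lexicon(seeds, db, top_k = k + 1)
    for (sid in paste0("S", 1:9)) {
      expect_true(all(a$term[a$symptom_id == sid] %in% b$term[b$symptom_id == sid]),
                  info = paste("top_k", k, sid))
    }
  }
})

test_that("lexicon pseudo-documents put seeds first, once each, deterministically", {
  lex <- expand_lexicon(read_seed_lexicon(), lexdb())
  expect_equal(lexicon_document(lex, "S9"), c("dead", "hurt", "suicide"))

  lex2 <- test_lexicon(top_k = 2)
  doc <- lexicon_document(lex2, "S9")
  expect_equal(doc[1:3], c("dead", "hurt", "suicide"))
  expect_equal(anyDuplicated(doc), 0)
  expect_identical(doc, lexicon_document(lex2, "S9"))
  # antonyms are excluded unless asked for
  expect_false(any(grepl("_anti$", doc)))
  doc_a <- lexicon_document(lex2, "S9", include_antonyms = TRUE)
  expect_true(any(grepl("_anti$", doc_a)))
  # a symptom whose lexicon is empty is an error
  empty <- lex2[lex2$symptom_id == "S9" & lex2$provenance == "antonym", ]
  expect_error(lexicon_document(empty, "S9"), "empty lexicon")
})

test_that("expanded lexicons round-trip through the TSV format", {
  lex <- test_lexicon(top_k = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_equal(back$term, lex$term)
  expect_equal(back$symptom_id, lex$symptom_id)
  expect_equal(back$provenance, lex$provenance)
})

test_that("lexical database lookups are case-insensitive and total", {
  db <- toy_lexdb()
  expect_equal(lexdb_lookup(db, "SLEEP", "synonym"), c("slumber", "nap", "rest"))
  expect_equal(lexdb_lookup(db, "unknown-word", "synonym"), character(0))
  expect_equal(lexdb_lookup(db, "sleep", "hyponym"), character(0))
  path <- withr::local_tempfile(fileext = ".json")
  write_lexdb_json(db, path)
  back <- read_lexdb_json(path)
  expect_equal(lexdb_lookup(back, "sleep", "antonym"), "wakefulness")
})
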