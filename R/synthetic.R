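# Deterministic RNG scoping: every generator takes a seed, runs under its own
# substream, and restores the caller's RNG state.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% 2147483647L, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Independent substreams per component, so e.g. the vector fixture can be
# regenerated without re-drawing the corpus.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Specification of a synthetic forum corpus
#'
#' Captures the generating conditions for [generate_corpus()]: corpus size,
#' per-symptom prevalence, planted-signal strength, filler-vocabulary size
#' and post length. Defaults emulate the scale of the study corpus the
#' pipeline targets (about 232 words and 9 sentences per post) with a
#' moderate 30% per-symptom prevalence and a strong planted signal of
#' `signal = 3` (each positive symptom plants `Poisson(signal) + 1` lexicon
#' terms).
#'
#' @param n_posts Number of posts.
#' @param prevalence Per-symptom presence probability; a single value or a
#'   length-9 vector (order S1..S9).
#' @param signal Expected extra planted terms per positive symptom (the
#'   planted count is `Poisson(signal) + 1`).
#' @param filler_vocab Number of distinct content filler words (function
#'   words are added on top as the high-frequency head; see Details).
#' @param mean_words,mean_sentences Target mean post length in words and
#'   sentences.
#' @param zipf_exponent Exponent of the Zipf-like filler frequency law.
#' @param label_correlation In `[0, 1)`: strength of a shared latent
#'   "severity" that correlates symptom labels within a post (0 = independent
#'   Bernoulli draws).
#' @param seed Integer master seed; all components derive substreams from it.
#'
#' @details Filler text mimics the frequency profile of real forum prose: the
#' most frequent ranks are the closed-class [function_words()] (which POS
#' filtering later removes, exactly as in real text), followed by
#' `filler_vocab` neutral pseudo-words on the Zipf tail.
#'
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_posts = 2000, prevalence = 0.3, signal = 3,
                           filler_vocab = 500, mean_words = 232,
                           mean_sentences = 9, zipf_exponent = 1,
                           label_correlation = 0, seed = 1) {
  prevalence <- rep_len(prevalence, 9)
  stopifnot(n_posts >= 0, all(prevalence >= 0 & prevalence <= 1), signal >= 0,
            filler_vocab >= 1, mean_words >= 10,
            label_correlation >= 0, label_correlation < 1)
  structure(list(n_posts = as.integer(n_posts), prevalence = prevalence,
                 signal = signal, filler_vocab = as.integer(filler_vocab),
                 mean_words = mean_words, mean_sentences = mean_sentences,
                 zipf_exponent = zipf_exponent,
                 label_correlation = label_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Pronounceable neutral pseudo-words for the filler vocabulary tail.
filler_words <- function(n) {
  on1 <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  nuc <- c("a", "e", "i", "o", "u", "ai", "ee", "oa", "ou")
  cod <- c("n", "m", "l", "r", "s", "t", "k", "sh", "nd", "st")
  grid <- expand.grid(on1, nuc, cod, on1, nuc, stringsAsFactors = FALSE)
  words <- do.call(paste0, grid)
  words <- words[!duplicated(words)]
  if (n > length(words)) abort("filler vocabulary request too large.")
  words[seq_len(n)]
}

#' Generate a synthetic labeled forum corpus
#'
#' Draws the nine symptom labels per post (Bernoulli at the spec prevalence,
#' optionally correlated through a shared latent severity), then writes each
#' post as Zipf-sampled filler text with, for every positive symptom,
#' `Poisson(signal) + 1` terms sampled from that symptom's lexicon
#' interleaved at random positions. Sentence breaks are inserted to hit the
#' spec's sentences-per-post target. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param lexicon A `phq_lexicon`; planted terms are drawn from each
#'   symptom's [lexicon_document()] (antonyms excluded).
#' @param plant_provenance Restrict planted terms to these provenance tags,
#'   e.g. `"synonym"` to plant only expansion synonyms; default all
#'   non-antonym terms.
#' @return List with `posts` (tibble `post_id`, `text`, plus a `planted`
#'   list-column of the terms planted per post) and `truth` (label-matrix
#'   tibble).
#' @export
generate_corpus <- function(spec, lexicon, plant_provenance = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), is.data.frame(lexicon))
  lex <- lexicon[lexicon$provenance != "antonym", , drop = FALSE]
  if (!is.null(plant_provenance)) {
    lex <- lex[lex$provenance %in% plant_provenance, , drop = FALSE]
  }
  pools <- lapply(SYMPTOM_IDS, function(sid) lex$term[lex$symptom_id == sid])
  names(pools) <- SYMPTOM_IDS
  if (any(lengths(pools) == 0)) abort("every symptom needs at least one plantable term.")
  n <- spec$n_posts
  if (n == 0) {
    empty <- tibble::tibble(post_id = character(0), text = character(0),
                            planted = list())
    truth <- tibble::as_tibble(matrix(integer(0), 0, 9,
                                      dimnames = list(NULL, SYMPTOM_IDS)))
    return(list(posts = empty,
                truth = dplyr::bind_cols(tibble::tibble(post_id = character(0)), truth)))
  }
  fw <- function_words()
  vocab <- c(fw, filler_words(spec$filler_vocab))
  probs <- seq_along(vocab)^(-spec$zipf_exponent)
  probs <- probs / sum(probs)

  with_rng(derive_seed(spec$seed, 1L), {
    labels <- matrix(0L, n, 9, dimnames = list(NULL, SYMPTOM_IDS))
    if (spec$label_correlation > 0) {
      rho <- spec$label_correlation
      sev <- rnorm(n)
      for (k in 1:9) {
        z <- sqrt(rho) * sev + sqrt(1 - rho) * rnorm(n)
        labels[, k] <- as.integer(z < stats::qnorm(spec$prevalence[k]))
      }
    } else {
      for (k in 1:9) labels[, k] <- rbinom(n, 1, spec$prevalence[k])
    }
    texts <- character(n)
    planted <- vector("list", n)
    for (i in seq_len(n)) {
      len <- max(20L, round(rnorm(1, spec$mean_words, 0.15 * spec$mean_words)))
      toks <- sample(vocab, len, replace = TRUE, prob = probs)
      plant <- character(0)
      for (k in which(labels[i, ] == 1L)) {
        m <- rpois(1, spec$signal) + 1L
        plant <- c(plant, sample(pools[[k]], m, replace = TRUE))
      }
      if (length(plant) > 0) {
        pos <- sort(sample(length(toks) + length(plant), length(plant)))
        merged <- character(length(toks) + length(plant))
        merged[pos] <- plant
        merged[-pos] <- toks
        toks <- merged
      }
      texts[i] <- render_sentences(toks, spec$mean_sentences)
      planted[[i]] <- plant
    }
    ids <- sprintf("post%05d", seq_len(n))
    list(
      posts = tibble::tibble(post_id = ids, text = texts, planted = planted),
      truth = dplyr::bind_cols(tibble::tibble(post_id = ids),
                               tibble::as_tibble(labels))
    )
  })
}

# Break a token stream into roughly mean_sentences sentences ended by periods.
render_sentences <- function(tokens, mean_sentences) {
  n <- length(tokens)
  n_sent <- max(1L, round(mean_sentences))
  bounds <- unique(round(seq_len(n_sent) * n / n_sent))
  out <- character(0)
  start <- 1L
  for (b in bounds) {
    out <- c(out, paste(paste(tokens[start:b], collapse = " "), ".", sep = ""))
    start <- b + 1L
  }
  paste(out, collapse = " ")
}

#' Generate a clustered word-vector fixture
#'
#' Builds a `word_vector_table` in which each symptom's lexicon terms cluster
#' around a distinct anchor direction (anchors mutually orthogonal in
#' orthogonal mode) and filler words are isotropic unit vectors — the
#' geometry a well-trained embedding exhibits at caricature strength. A
#' term's vector is `(cohesion * anchor + z) / norm` with `z` a random unit
#' direction, so `cohesion` sets the within-cluster spread
#' (`cohesion = Inf` collapses each cluster onto its anchor exactly).
#'
#' @param lexicon A `phq_lexicon`; all its terms (antonyms included) receive
#'   clustered vectors.
#' @param dim Vector dimension (>= 9 in orthogonal mode); default 300, the
#'   conventional pre-trained GloVe dimension.
#' @param cohesion Cluster tightness; default 2 gives within-cluster pairwise
#'   cosines around 0.8, typical of close synonyms in distributional spaces.
#' @param extra_words Additional (filler) words to include as isotropic
#'   vectors; default: the generator's filler vocabulary plus function words.
#' @param n_filler Used when `extra_words` is `NULL`: size of the default
#'   filler vocabulary to cover.
#' @param orthogonal Draw mutually orthonormal anchors (default) or
#'   independent random unit anchors.
#' @param seed Integer seed.
#' @return A `word_vector_table` covering every lexicon term and filler word.
#' @export
generate_vector_fixture <- function(lexicon, dim = 300, cohesion = 2,
                                    extra_words = NULL, n_filler = 500,
                                    orthogonal = TRUE, seed = 1) {
  stopifnot(is.data.frame(lexicon), dim >= 2)
  if (orthogonal && dim < 9) abort("orthogonal-cluster mode needs dim >= 9.")
  extra_words <- extra_words %||% c(function_words(), filler_words(n_filler))
  with_rng(derive_seed(seed, 2L), {
    anchors <- if (orthogonal) {
      qr.Q(qr(matrix(rnorm(dim * 9), dim, 9)))
    } else {
      a <- matrix(rnorm(dim * 9), dim, 9)
      sweep(a, 2, sqrt(colSums(a^2)), `/`)
    }
    colnames(anchors) <- SYMPTOM_IDS
    lex <- lexicon[!duplicated(lexicon$term), , drop = FALSE]
    fill <- setdiff(unique(extra_words), lex$term)
    words <- c(lex$term, fill)
    vecs <- matrix(0, length(words), dim)
    for (i in seq_len(nrow(lex))) {
      a <- anchors[, lex$symptom_id[i]]
      if (is.infinite(cohesion)) {
        vecs[i, ] <- a
      } else {
        z <- rnorm(dim)
        z <- z / sqrt(sum(z^2))
        v <- cohesion * a + z
        vecs[i, ] <- v / sqrt(sum(v^2))
      }
    }
    for (j in seq_along(fill)) {
      z <- rnorm(dim)
      vecs[nrow(lex) + j, ] <- z / sqrt(sum(z^2))
    }
    word_vector_table(vecs, words)
  })
}

#' Generate a miniature lexical database fixture
#'
#' Maps every seed term of every symptom to a few synthetic related terms
#' (per seed: 2-4 synonyms, one hypernym, one antonym), named by suffixing
#' the seed (e.g. `sleep_syn1`, `sleep_kind`, `sleep_anti`). Because the
#' derived names carry their symptom through [expand_lexicon()] into
#' [generate_vector_fixture()], the database is consistent with the vector
#' fixture's clusters.
#'
#' @param seeds Seed lexicon tibble from [read_seed_lexicon()].
#' @param seed Integer seed (controls the per-seed synonym counts).
#' @return A [lexdb()].
#' @export
mini_lexical_db <- function(seeds = read_seed_lexicon(), seed = 1) {
  stopifnot(is.data.frame(seeds))
  with_rng(derive_seed(seed, 3L), {
    entries <- list()
    for (i in seq_len(nrow(seeds))) {
      for (s in seeds$seeds[[i]]) {
        n_syn <- sample(2:4, 1)
        entries[[s]] <- list(
          synonym = paste0(s, "_syn", seq_len(n_syn)),
          hypernym = paste0(s, "_kind"),
          antonym = paste0(s, "_anti")
        )
      }
    }
    lexdb(entries)
  })
}
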