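# Packaged replication experiments: each function builds its own synthetic
# study (lexicon, fixtures, corpus), runs one part of the pipeline, and
# returns the measured quantities. The test suite and scripts/acceptance.R
# are thin wrappers around these.

#' Standard synthetic study assets
#'
#' Builds the canonical synthetic study used by the replication experiments:
#' expanded lexicon (seed terms expanded through the miniature lexical
#' database), the 300-dimensional clustered vector fixture, a generated
#' corpus with planted-truth labels, and the preprocessed corpus.
#'
#' @param n_posts Corpus size.
#' @param seed Integer seed (drives db, fixture and corpus substreams).
#' @param signal Planted-signal strength (see [synthetic_spec()]).
#' @param prevalence Per-symptom prevalence.
#' @param plant_provenance Optional provenance restriction for planted terms
#'   (e.g. `"synonym"`).
#' @return List with `lexicon`, `db`, `vectors` (300-d fixture), `corpus`
#'   (preprocessed tibble), `posts`, `truth`.
#' @export
synthetic_study <- function(n_posts = 2000, seed = 1, signal = 3,
                            prevalence = 0.3, plant_provenance = NULL) {
  seeds <- read_seed_lexicon()
  db <- mini_lexical_db(seeds, seed = seed)
  lex <- expand_lexicon(seeds, db, top_k = 5)
  vt <- generate_vector_fixture(lex, dim = 300, seed = seed)
  spec <- synthetic_spec(n_posts = n_posts, prevalence = prevalence,
                         signal = signal, seed = seed)
  corp <- generate_corpus(spec, lex, plant_provenance = plant_provenance)
  corpus <- preprocess_corpus(corp$posts[, c("post_id", "text")])
  list(lexicon = lex, db = db, vectors = vt, corpus = corpus,
       posts = corp$posts, truth = corp$truth)
}

#' Weak-labeler recovery experiment
#'
#' Generates a corpus with planted symptom terms, scores it with the
#' cosine-similarity weak labeler against the expanded lexicons, and
#' measures the per-symptom ranking AUC against the planted truth.
#'
#' @inheritParams synthetic_study
#' @return Tibble with `symptom_id` and `auc`, with the generating seed and
#'   corpus size as attributes.
#' @export
weak_recovery_experiment <- function(n_posts = 2000, seed = 1, signal = 3,
                                     prevalence = 0.3) {
  st <- synthetic_study(n_posts = n_posts, seed = seed, signal = signal,
                        prevalence = prevalence)
  profiles <- similarity_profiles(st$corpus, st$lexicon, st$vectors)
  truth <- label_matrix_values(st$truth)
  out <- tibble::tibble(
    symptom_id = SYMPTOM_IDS,
    auc = vapply(SYMPTOM_IDS, function(sid) {
      roc_auc(profiles[[sid]], truth[, sid])
    }, 0)
  )
  attr(out, "n_posts") <- n_posts
  attr(out, "seed") <- seed
  out
}

#' Synonym-expansion benefit experiment
#'
#' The package's test of the claim that lexical expansion improves weak
#' supervision: posts are planted with *synonym* terms only (never the
#' seeds), then scored once against the expanded lexicons and once against
#' the seeds-only lexicons. If expansion carries signal, the expanded-lexicon
#' mean AUC must exceed the seeds-only mean AUC on the same corpus.
#'
#' @param seeds_ Integer vector of replicate seeds.
#' @param n_posts Corpus size per replicate.
#' @return Tibble with one row per replicate: `seed`, `expanded_auc`,
#'   `seeds_only_auc`, `difference`.
#' @export
expansion_benefit_experiment <- function(seeds_ = 1:5, n_posts = 800) {
  rows <- lapply(seeds_, function(sd) {
    st <- synthetic_study(n_posts = n_posts, seed = sd,
                          plant_provenance = "synonym")
    seeds_only <- seeds_only_lexicon()
    truth <- label_matrix_values(st$truth)
    mean_auc_for <- function(lex) {
      prof <- similarity_profiles(st$corpus, lex, st$vectors)
      mean(vapply(SYMPTOM_IDS, function(sid) roc_auc(prof[[sid]], truth[, sid]), 0))
    }
    tibble::tibble(seed = sd,
                   expanded_auc = mean_auc_for(st$lexicon),
                   seeds_only_auc = mean_auc_for(seeds_only))
  })
  dplyr::mutate(dplyr::bind_rows(rows),
                difference = .data$expanded_auc - .data$seeds_only_auc)
}

# Calibrated weak labels for a study, anchored on the first `n_gold` posts
# (the synthetic stand-in for a small human-annotated subset).
study_weak_labels <- function(st, n_gold = 100) {
  profiles <- similarity_profiles(st$corpus, st$lexicon, st$vectors)
  anchor <- profiles[seq_len(n_gold), ]
  gold <- st$truth[seq_len(n_gold), ]
  thr <- calibrate_thresholds(anchor, gold)
  list(profiles = profiles, thresholds = thr,
       labels = binarize(profiles, thr$threshold))
}

#' Model-ordering experiment
#'
#' One replicate of the architecture comparison: generate the synthetic
#' corpus, weak-label it (cosine profiles binarized at thresholds calibrated
#' on a 100-post gold anchor), train the requested architectures on the
#' weak labels of the training split, and measure mean test ROC against the
#' planted truth. Recurrent models consume the corpus-trained 16-dimensional
#' domain embedding ([train_domain_embedding()]); the feedforward baseline
#' consumes its mean-pooled post vectors. Also reports the attention
#' localization rate: the fraction of positive test posts whose mean
#' attention weight on planted symptom tokens exceeds the mean weight on
#' filler tokens.
#'
#' @param seed Replicate seed.
#' @param n_posts Corpus size (split 80/20 into train/test).
#' @param kinds Architectures to train.
#' @param epochs,batch_size,hidden_size,max_len Reduced-scale training
#'   conditions (defaults: 30 epochs, batch 1, H = 16, 48 tokens).
#' @param embedding_dim Domain-embedding dimension (default 16).
#' @return List with `auc` (named mean test AUC per architecture),
#'   `localization` (attention localization rate, if
#'   `"bilstm_attention"` is trained), `models`, and the study assets.
#' @export
model_ordering_experiment <- function(seed = 1, n_posts = 2000,
                                      kinds = c("baseline", "bilstm_attention"),
                                      epochs = 30, batch_size = 1,
                                      hidden_size = 16, max_len = 48,
                                      embedding_dim = 16) {
  st <- synthetic_study(n_posts = n_posts, seed = 1000 + seed)
  wl <- study_weak_labels(st)
  ywk <- label_matrix_values(wl$labels)
  truth <- label_matrix_values(st$truth)
  n <- nrow(st$corpus)
  tr <- seq_len(floor(0.8 * n))
  te <- setdiff(seq_len(n), tr)

  vocab <- sort(union(unique(unlist(st$corpus$content_tokens)),
                      unique(st$lexicon$term)))
  dom <- train_domain_embedding(st$corpus, vocabulary = vocab,
                                dim = embedding_dim, window = 5)
  seqs <- post_sequences(st$corpus, dom, max_len = max_len)
  x <- post_mean_embeddings(st$corpus, dom)

  cfg <- train_config(max_epochs = epochs, batch_size = batch_size,
                      hidden_size = hidden_size, seed = seed)
  aucs <- c()
  models <- list()
  localization <- NA_real_
  for (kind in kinds) {
    input_tr <- if (kind == "baseline") x[tr, , drop = FALSE] else seqs[tr]
    input_te <- if (kind == "baseline") x[te, , drop = FALSE] else seqs[te]
    m <- train_model(input_tr, ywk[tr, , drop = FALSE], kind, cfg)
    probs <- predict_proba(m, input_te)
    aucs[kind] <- suppressWarnings(mean_roc(probs, truth[te, , drop = FALSE])$mean_auc)
    models[[kind]] <- m
    if (kind == "bilstm_attention") {
      aw <- attention_weights(m, seqs[te])
      toks <- attr(seqs, "tokens")[te]
      planted <- st$posts$planted[te]
      hits <- mapply(function(w, tk, pl) {
        on <- tk %in% pl
        if (!any(on) || all(on)) return(NA)
        mean(w[on]) > mean(w[!on])
      }, aw, toks, planted)
      localization <- mean(hits, na.rm = TRUE)
    }
  }
  list(auc = aucs, localization = localization, models = models,
       weak_labels = wl, study = st, train_idx = tr, test_idx = te,
       domain_embedding = dom, sequences = seqs)
}

#' Active-learning comparison experiment
#'
#' One replicate of the entropy-vs-random acquisition comparison at matched
#' label budgets: both strategies start from the same initial labeled set,
#' acquire the same number of weak labels per round, and are scored on the
#' same held-out validation set against the planted truth after every round.
#'
#' @param seed Replicate seed.
#' @param n_posts Corpus size.
#' @param init_n Initially labeled posts.
#' @param batch_k Labels acquired per round.
#' @param rounds Maximum acquisition rounds.
#' @param val_n Validation posts (taken from the corpus tail).
#' @param epochs Training epochs per round (baseline architecture on the
#'   300-d fixture mean embeddings).
#' @param oracle `"truth"` (default): selected posts are labeled with their
#'   true labels, simulating the human annotator whose effort the loop is
#'   meant to save, so the label budget measures annotation cost.
#'   `"weak"`: the weak labeler provides the labels, as in the deployed
#'   pipeline.
#' @return Tibble with columns `acquisition`, `round`, `n_labeled`,
#'   `val_auc`.
#' @export
al_comparison_experiment <- function(seed = 1, n_posts = 1200, init_n = 100,
                                     batch_k = 200, rounds = 4, val_n = 300,
                                     epochs = 150,
                                     oracle = c("truth", "weak")) {
  oracle <- match.arg(oracle)
  st <- synthetic_study(n_posts = n_posts, seed = 2000 + seed)
  wl <- study_weak_labels(st)
  x <- post_mean_embeddings(st$corpus, st$vectors)
  ids <- st$corpus$post_id
  val_ids <- tail(ids, val_n)
  work_ids <- setdiff(ids, val_ids)
  source_labels <- if (oracle == "truth") st$truth else wl$labels
  labeler <- function(sel) source_labels[match(sel, source_labels$post_id), ]
  # every acquired label is used for fitting; rounds run their full epochs
  cfg <- train_config(max_epochs = epochs, batch_size = 8, val_fraction = 0,
                      seed = seed)
  out <- lapply(c("entropy", "random"), function(acq) {
    al <- active_loop(x[work_ids, , drop = FALSE], labeler,
                      initial_ids = head(work_ids, init_n),
                      val_x = x[val_ids, , drop = FALSE],
                      val_labels = st$truth[match(val_ids, st$truth$post_id), ],
                      model_kind = "baseline", config = cfg,
                      rounds = rounds, batch_k = batch_k,
                      acquisition = acq, metric_patience = rounds + 1L)
    dplyr::mutate(tidy(al), acquisition = acq)
  })
  dplyr::bind_rows(out)[, c("acquisition", "round", "n_labeled", "val_auc")]
}

#' First label budget at which a learning curve reaches a target
#'
#' @param history Tibble from [al_comparison_experiment()] filtered to one
#'   acquisition strategy.
#' @param target Validation mean-AUC target.
#' @return The smallest `n_labeled` whose `val_auc` meets the target
#'   (`Inf` if never reached).
#' @export
budget_to_reach <- function(history, target = 0.8) {
  hit <- history$n_labeled[history$val_auc >= target]
  if (length(hit) == 0) Inf else min(hit)
}
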