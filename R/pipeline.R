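# Unified pipeline entry point shared by the R API and the command-line
# wrapper in inst/exec/phqminer.

# Allowed configuration schema: NULL marks a leaf whose value is caller-chosen.
config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, verbose = NULL,
    paths = list(corpus = NULL, seed_lexicon = NULL, lexicon = NULL,
                 vectors = NULL, lexdb = NULL, gold = NULL, truth = NULL,
                 model = NULL, labels = NULL, predictions = NULL),
    lexicon = list(top_k = NULL, include_antonyms = NULL),
    synthetic = list(n_posts = NULL, prevalence = NULL, signal = NULL,
                     filler_vocab = NULL, mean_words = NULL,
                     mean_sentences = NULL, label_correlation = NULL,
                     vector_dim = NULL, cohesion = NULL),
    label = list(threshold = NULL, calibrate = NULL, use_content_tokens = NULL),
    train = list(arch = NULL, epochs = NULL, learning_rate = NULL,
                 dropout = NULL, batch_size = NULL, hidden_size = NULL,
                 grad_clip_norm = NULL, patience = NULL, max_len = NULL,
                 test_fraction = NULL),
    active = list(rounds = NULL, batch_k = NULL, init_n = NULL,
                  acquisition = NULL, val_n = NULL),
    visualize = list(top_n = NULL, n_posts = NULL)
  )
}

validate_config <- function(config, schema = config_schema(), prefix = "") {
  stopifnot(is.list(config))
  for (key in names(config)) {
    full <- paste0(prefix, key)
    if (!key %in% names(schema)) {
      abort(paste0("unknown configuration key: '", full, "'."))
    }
    if (is.list(schema[[key]]) && length(schema[[key]]) > 0) {
      if (!is.list(config[[key]])) {
        abort(paste0("configuration key '", full, "' must be a section."))
      }
      validate_config(config[[key]], schema[[key]], paste0(full, "."))
    }
  }
  invisible(config)
}

cfg_get <- function(config, path, default = NULL) {
  node <- config
  for (key in path) {
    node <- node[[key]]
    if (is.null(node)) return(default)
  }
  node
}

#' Read a pipeline configuration file
#'
#' Configurations are YAML with a fixed schema (seed, output directory, file
#' paths, and per-stage option sections); unknown keys are rejected, naming
#' the first offender.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  validate_config(yaml::read_yaml(path))
}

require_path <- function(config, key, stage) {
  p <- cfg_get(config, c("paths", key))
  if (is.null(p)) {
    abort(paste0("stage '", stage, "' requires paths.", key, " in the configuration."))
  }
  if (!file.exists(p)) abort(paste0("input file not found: ", p, " (paths.", key, ")."))
  p
}

pipeline_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[phqminer] ", ...)
  invisible(NULL)
}

# Plain-text model checkpoints: a JSON manifest with all parameter arrays.
#' Save and load fitted models
#'
#' Checkpoints are plain-text JSON holding the architecture, configuration
#' and all parameter arrays in full double precision.
#'
#' @param model A fitted `phq_model`.
#' @param path Checkpoint file path (JSON).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `phq_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "phq_model"))
  payload <- list(
    kind = model$kind,
    input_dim = model$input_dim,
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    n_train = model$n_train, n_val = model$n_val,
    log = model$log,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = NULL, values = as.numeric(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model checkpoint not found: ", path))
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) matrix(p$values, p$dim[1], p$dim[2])
    else as.numeric(p$values)
  })
  attr(params, "kind") <- payload$kind
  cfg <- payload$config
  config <- train_config(
    learning_rate = cfg$learning_rate, dropout = cfg$dropout,
    max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
    patience = cfg$patience, grad_clip_norm = cfg$grad_clip_norm,
    val_fraction = cfg$val_fraction, hidden_size = cfg$hidden_size,
    min_delta = cfg$min_delta, seed = cfg$seed
  )
  structure(list(kind = payload$kind, params = params, config = config,
                 input_dim = payload$input_dim, n_train = payload$n_train,
                 n_val = payload$n_val, best_epoch = payload$best_epoch,
                 best_val_loss = payload$best_val_loss,
                 log = tibble::as_tibble(payload$log)),
            class = "phq_model")
}

#' Run a pipeline stage
#'
#' The programmatic pipeline entry point behind the `phqminer` command-line
#' script. Each stage reads its inputs from `config$paths`, writes its
#' artifacts under `config$out_dir`, and echoes the resolved configuration to
#' `manifest.yaml` there, so a run is reproducible from its manifest alone.
#'
#' Stages: `simulate` (synthetic corpus + fixtures), `lexicon` (seed
#' expansion), `label` (weak labeling), `train` (fit a classifier on a
#' labeled corpus), `active` (entropy-driven acquisition loop), `evaluate`
#' (per-symptom AUC report), `visualize` (attention HTML).
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   YAML file.
#' @param stage One of the stage names above.
#' @return Invisibly, a list of the artifact paths written.
#' @export
run_pipeline <- function(config, stage = c("simulate", "lexicon", "label",
                                           "train", "active", "evaluate",
                                           "visualize")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  out_dir <- cfg_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_get(config, "seed", 1L)
  verbose <- cfg_get(config, "verbose", TRUE)
  artifacts <- list()
  t0 <- Sys.time()

  if (stage == "simulate") {
    seeds <- read_seed_lexicon(cfg_get(config, c("paths", "seed_lexicon")))
    db <- mini_lexical_db(seeds, seed = seed)
    lex <- expand_lexicon(seeds, db, top_k = cfg_get(config, c("lexicon", "top_k"), 5))
    spec <- synthetic_spec(
      n_posts = cfg_get(config, c("synthetic", "n_posts"), 2000),
      prevalence = cfg_get(config, c("synthetic", "prevalence"), 0.3),
      signal = cfg_get(config, c("synthetic", "signal"), 3),
      filler_vocab = cfg_get(config, c("synthetic", "filler_vocab"), 500),
      mean_words = cfg_get(config, c("synthetic", "mean_words"), 232),
      mean_sentences = cfg_get(config, c("synthetic", "mean_sentences"), 9),
      label_correlation = cfg_get(config, c("synthetic", "label_correlation"), 0),
      seed = seed
    )
    corp <- generate_corpus(spec, lex)
    vt <- generate_vector_fixture(
      lex, dim = cfg_get(config, c("synthetic", "vector_dim"), 300),
      cohesion = cfg_get(config, c("synthetic", "cohesion"), 2),
      n_filler = spec$filler_vocab, seed = seed
    )
    artifacts$corpus <- file.path(out_dir, "corpus.jsonl")
    write_corpus_jsonl(dplyr::select(corp$posts, "post_id", "text"), artifacts$corpus)
    artifacts$truth <- file.path(out_dir, "truth.csv")
    write_label_csv(corp$truth, artifacts$truth)
    artifacts$lexicon <- file.path(out_dir, "lexicon.tsv")
    write_lexicon(lex, artifacts$lexicon)
    artifacts$lexdb <- file.path(out_dir, "lexdb.json")
    write_lexdb_json(db, artifacts$lexdb)
    artifacts$vectors <- file.path(out_dir, "vectors.txt")
    write_word_vectors(vt, artifacts$vectors)
    pipeline_log(verbose, "simulate: wrote ", nrow(corp$posts), " posts.")
  } else if (stage == "lexicon") {
    seeds <- read_seed_lexicon(cfg_get(config, c("paths", "seed_lexicon")))
    db <- read_lexdb_json(require_path(config, "lexdb", stage))
    lex <- expand_lexicon(seeds, db, top_k = cfg_get(config, c("lexicon", "top_k"), 5))
    artifacts$lexicon <- file.path(out_dir, "lexicon.tsv")
    write_lexicon(lex, artifacts$lexicon)
    pipeline_log(verbose, "lexicon: ", nrow(lex), " terms across 9 symptoms.")
  } else if (stage == "label") {
    posts <- read_corpus_jsonl(require_path(config, "corpus", stage))
    lex <- read_lexicon(require_path(config, "lexicon", stage))
    vt <- read_word_vectors(require_path(config, "vectors", stage))
    res <- weak_label_corpus(
      posts, lex, vt,
      threshold = cfg_get(config, c("label", "threshold"), 0.5),
      use_content_tokens = cfg_get(config, c("label", "use_content_tokens"), TRUE)
    )
    if (isTRUE(cfg_get(config, c("label", "calibrate")))) {
      gold <- read_label_csv(require_path(config, "gold", stage))
      anchor <- res$profiles[res$profiles$post_id %in% gold$post_id, ]
      thr <- calibrate_thresholds(anchor, gold)
      res$labels <- binarize(res$profiles, thr$threshold)
      artifacts$thresholds <- file.path(out_dir, "thresholds.csv")
      utils::write.csv(as.data.frame(thr[, c("symptom_id", "threshold")]),
                       artifacts$thresholds, row.names = FALSE)
    }
    artifacts$labels <- file.path(out_dir, "labels.csv")
    write_label_csv(res$labels, artifacts$labels)
    artifacts$scored <- file.path(out_dir, "scored.jsonl")
    scored <- dplyr::mutate(
      dplyr::left_join(posts[, c("post_id", "text")], res$labels, by = "post_id"),
      scores = lapply(seq_len(nrow(res$profiles)), function(i) {
        as.numeric(res$profiles[i, SYMPTOM_IDS])
      })
    )
    write_corpus_jsonl(scored, artifacts$scored)
    pipeline_log(verbose, "label: ", nrow(res$labels), " posts scored.")
  } else if (stage == "train") {
    posts <- read_corpus_jsonl(require_path(config, "corpus", stage))
    labels <- read_label_csv(require_path(config, "labels", stage))
    vt <- read_word_vectors(require_path(config, "vectors", stage))
    arch <- cfg_get(config, c("train", "arch"), "bilstm_attention")
    cfgt <- train_config(
      learning_rate = cfg_get(config, c("train", "learning_rate"), 5e-4),
      dropout = cfg_get(config, c("train", "dropout"), 0.5),
      max_epochs = cfg_get(config, c("train", "epochs"), 30),
      batch_size = cfg_get(config, c("train", "batch_size"), 8),
      hidden_size = cfg_get(config, c("train", "hidden_size"), 16),
      grad_clip_norm = cfg_get(config, c("train", "grad_clip_norm"), 1),
      patience = cfg_get(config, c("train", "patience"), 10),
      seed = seed
    )
    corpus <- preprocess_corpus(posts[, c("post_id", "text")])
    labels <- labels[match(corpus$post_id, labels$post_id), ]
    x <- if (arch == "baseline") post_mean_embeddings(corpus, vt)
         else post_sequences(corpus, vt,
                             max_len = cfg_get(config, c("train", "max_len")))
    model <- train_model(x, labels, arch, cfgt)
    artifacts$model <- file.path(out_dir, "model.json")
    save_model(model, artifacts$model)
    artifacts$log <- file.path(out_dir, "training_log.csv")
    utils::write.csv(as.data.frame(model$log), artifacts$log, row.names = FALSE)
    pipeline_log(verbose, "train: ", arch, ", ", nrow(model$log), " epochs.")
  } else if (stage == "evaluate") {
    posts <- read_corpus_jsonl(require_path(config, "corpus", stage))
    truth <- read_label_csv(require_path(config, "truth", stage))
    vt <- read_word_vectors(require_path(config, "vectors", stage))
    model <- load_model(require_path(config, "model", stage))
    corpus <- preprocess_corpus(posts[, c("post_id", "text")])
    x <- if (model$kind == "baseline") post_mean_embeddings(corpus, vt)
         else post_sequences(corpus, vt,
                             max_len = cfg_get(config, c("train", "max_len")))
    probs <- predict_proba(model, x)
    truth <- truth[match(corpus$post_id, truth$post_id), ]
    roc <- mean_roc(probs, truth)
    artifacts$metrics <- file.path(out_dir, "metrics.csv")
    report <- tidy(roc)
    report <- dplyr::bind_rows(report,
                               tibble::tibble(symptom_id = "mean", auc = roc$mean_auc))
    utils::write.csv(as.data.frame(report), artifacts$metrics, row.names = FALSE)
    pipeline_log(verbose, "evaluate: mean AUC ", round(roc$mean_auc, 4), ".")
  } else if (stage == "active") {
    posts <- read_corpus_jsonl(require_path(config, "corpus", stage))
    labels <- read_label_csv(require_path(config, "labels", stage))
    truth <- read_label_csv(require_path(config, "truth", stage))
    vt <- read_word_vectors(require_path(config, "vectors", stage))
    corpus <- preprocess_corpus(posts[, c("post_id", "text")])
    x <- post_mean_embeddings(corpus, vt)
    n <- nrow(corpus)
    val_n <- cfg_get(config, c("active", "val_n"), max(50L, round(0.15 * n)))
    init_n <- cfg_get(config, c("active", "init_n"), max(20L, round(0.05 * n)))
    ids <- corpus$post_id
    val_ids <- tail(ids, val_n)
    work_ids <- setdiff(ids, val_ids)
    al <- active_loop(
      x[work_ids, , drop = FALSE],
      labeler = function(sel) labels[match(sel, labels$post_id), ],
      initial_ids = head(work_ids, init_n),
      val_x = x[val_ids, , drop = FALSE],
      val_labels = truth[match(val_ids, truth$post_id), ],
      model_kind = "baseline",
      config = train_config(seed = seed, batch_size = 8),
      rounds = cfg_get(config, c("active", "rounds"), 8),
      batch_k = cfg_get(config, c("active", "batch_k"), 100),
      acquisition = cfg_get(config, c("active", "acquisition"), "entropy")
    )
    artifacts$history <- file.path(out_dir, "al_history.csv")
    utils::write.csv(as.data.frame(tidy(al)), artifacts$history, row.names = FALSE)
    artifacts$model <- file.path(out_dir, "al_model.json")
    save_model(al$model, artifacts$model)
    pipeline_log(verbose, "active: ", nrow(al$history), " rounds, best val AUC ",
                 round(max(al$history$val_auc), 4), ".")
  } else if (stage == "visualize") {
    posts <- read_corpus_jsonl(require_path(config, "corpus", stage))
    vt <- read_word_vectors(require_path(config, "vectors", stage))
    model <- load_model(require_path(config, "model", stage))
    if (model$kind != "bilstm_attention") {
      abort("visualize requires a bilstm_attention model checkpoint.")
    }
    n_show <- min(cfg_get(config, c("visualize", "n_posts"), 5), nrow(posts))
    corpus <- preprocess_corpus(posts[seq_len(n_show), c("post_id", "text")])
    seqs <- post_sequences(corpus, vt,
                           max_len = cfg_get(config, c("train", "max_len")))
    aw <- attention_weights(model, seqs)
    toks <- attr(seqs, "tokens")
    renderings <- lapply(seq_len(n_show), function(i) {
      render_attention(toks[[i]], aw[[i]],
                       top_n = cfg_get(config, c("visualize", "top_n"), 5))
    })
    artifacts$html <- file.path(out_dir, "attention.html")
    attention_html(renderings, artifacts$html)
    pipeline_log(verbose, "visualize: wrote ", n_show, " post(s).")
  }

  config$seed <- seed
  manifest <- list(stage = stage, config = config,
                   artifacts = lapply(artifacts, normalizePath, mustWork = FALSE),
                   elapsed_secs = round(as.numeric(difftime(Sys.time(), t0,
                                                            units = "secs")), 2))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(artifacts)
}
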