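# Shared fixtures built in code: a toy lexical database, small vector tables
# and independent oracles used across test files.

toy_lexdb <- function() {
  lexdb(list(
    sleep = list(synonym = c("slumber", "nap", "rest"),
                 hypernym = c("state"),
                 antonym = c("wakefulness")),
    dead = list(synonym = c("deceased", "lifeless")),
    sad = list(synonym = c("unhappy"))
  ))
}

# A vector table where each listed word gets an assigned vector.
fixed_vector_table <- function(vectors) {
  word_vector_table(do.call(rbind, vectors), names(vectors))
}

# Brute-force AUC oracle: enumerate all positive-negative pairs.
pair_counting_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Scalar binary-entropy oracle.
binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log(p) - (1 - p) * log(1 - p)
}

# Default study-scale fixtures at test size, shared by several files.
test_lexicon <- function(top_k = 5, seed = 1) {
  seeds <- read_seed_lexicon()
  db <- mini_lexical_db(seeds, seed = seed)
  expand_lexicon(seeds, db, top_k = top_k)
}
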