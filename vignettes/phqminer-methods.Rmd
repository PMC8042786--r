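---
title: "Detecting PHQ-9 symptoms in forum text: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PHQ-9 symptoms in forum text: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phqminer turns patient-authored forum posts into per-post predictions for
the nine PHQ-9 depression symptoms (S1 anhedonia through S9 self-harm
ideation). Human annotation of such text is slow and sensitive, so the
package's central idea is to manufacture labels: a hand-curated seed lexicon
per symptom is expanded through a lexical database, posts and lexicons are
embedded in a common vector space, and the cosine similarity between a
post's mean word vector and each symptom lexicon's mean word vector becomes
a weak symptom score. Binarized scores train neural multi-label
classifiers, and an entropy-driven active-learning loop decides which
unlabeled posts enter the training set next. This vignette records the
modelling choices, their rationale, and what the synthetic evaluation can
and cannot show.

## The weak labeler

For post $t$ with content tokens $w_1,\dots,w_n$ and word-vector table $V$,
the post embedding is $X = \frac{1}{n}\sum_i V[w_i]$, and each symptom $k$
gets $Y_k$, the mean vector of its lexicon's terms. The score is
$\max(0, \cos(X, Y_k))$. Cosine ranges over $[-1, 1]$; scores are reported
on $[0,1]$, and we clip negatives to zero rather than rescale
$(1+\cos)/2$, because rescaling would give text orthogonal to a symptom a
score of 0.5, implying spurious partial evidence.

Only content words (nouns, verbs, adjectives, adverbs) enter the post
embedding. The shipped part-of-speech backend is a deterministic
closed-class list: tokens on the `function_words()` list are dropped,
everything else is treated as an open-class content word. This is the one
distinction the pipeline needs, it requires no model download, and it is
exactly reproducible; a dictionary tagger or any external tagger can be
plugged in instead.

Binarization needs a threshold, and no universal value exists: raw cosine
scores live on a scale that depends on the embedding. The default is 0.5,
but the intended use is `calibrate_thresholds()`: given a small
human-labeled anchor set (a few dozen posts per symptom suffice), it picks
the per-symptom threshold maximizing Youden's $J$ (TPR $-$ FPR), ties going
to the lowest threshold. This mirrors the study design the pipeline is
built for, where a few hundred annotated posts anchor the automatic
labeling of the remainder. Both global and per-symptom thresholds are
supported; calibration is per-symptom because score scales differ across
lexicons of different sizes.

## Lexicon expansion

Each symptom's seed terms (e.g. S3: *sleep, asleep*; S9: *dead, hurt,
suicide*) are expanded through a pluggable lexical database exposing
synonym, hypernym, hyponym and antonym relations. The expansion depth is
the top 5 ranked terms per seed and relation — deeper expansion drifts off
topic — and duplicates are skipped, so expansion is monotone in the depth
parameter. Antonyms are extracted and stored with provenance, but excluded
from the similarity pseudo-document by default: an antonym of a symptom
term signals the symptom's absence, and mixing it into the symptom's
embedding would pull the lexicon centroid toward its opposite. Multi-word
database entries are kept as single underscore-joined tokens and match
only identically joined corpus tokens, avoiding spurious unigram hits.
The seed list itself is treated as pre-expansion: expansion happens at run
time against whatever database is configured.

## Embeddings

Two vector sources are supported and interchangeable behind
`word_vector_table`: pre-trained vectors loaded from word2vec/GloVe text
files (300-dimensional pre-trained vectors are the conventional choice),
and a corpus-trained domain embedding. The domain embedding is
PPMI-factorised: symmetric windowed co-occurrence counts (window 5, a
standard default) over the emotion vocabulary — the corpus's content words
plus their lexical expansions — transformed to positive pointwise mutual
information and factorised by rank-$\delta$ truncated SVD, word vectors
being the left singular vectors scaled by the square root of their singular
values. This estimator is deterministic (singular-vector signs are fixed by
convention), desk-scale, and needs no training infrastructure; a config
hook allows substituting an external skip-gram trainer. Out-of-vocabulary
tokens contribute nothing to mean pooling; an all-OOV post gets the zero
vector and a zero similarity profile, with a warning.

Where both pre-trained and corpus-trained vectors are available the
package does not merge them; the vector source is an explicit
configuration choice per pipeline stage. In the packaged replication
experiments the weak labeler uses the high-dimensional clustered fixture
(playing the role of pre-trained vectors) while the sequence classifiers
consume the 16-dimensional corpus-trained embedding — the same division of
labour as labeling with a general-purpose embedding and classifying with a
compact domain-adapted one.

## Classifiers

Four architectures are implemented from their defining equations, with
analytic gradients checked against numerical differentiation in the test
suite:

* **baseline** — feedforward on the mean-pooled post vector: three ReLU
  layers of 30, 20 and 10 units, then a 9-unit sigmoid output, one
  probability per symptom.
* **lstm** — unidirectional recurrent encoder; per-step states are
  mean-pooled over time (empirically stronger than taking the final state).
* **bilstm** — forward and backward encoders; each position's state is the
  concatenation of the two directions (size $2H$), mean-pooled.
* **bilstm_attention** — the bidirectional encoder pooled by a learned
  attention layer: $v_t = \tanh(h_t W_a + b_a)$, $s_t = v_t u_a^\top$,
  $\alpha = \mathrm{softmax}(s)$, $\tilde h = \sum_t \alpha_t h_t$. The
  weights $\alpha_t$ double as the per-token importance used by the
  visualisation functions.

The recurrent cell follows the four gate equations with per-gate input and
recurrent weight matrices and no gate biases. The candidate cell state uses
its own weights $W^{(c)}, U^{(c)}$ (the standard cell; sharing them with
the output gate would make the candidate redundant with the gate). The loss
is multi-label binary cross-entropy summed over the nine sigmoid outputs
and averaged over the batch — the only form consistent with nine
independent symptom indicators per post.

Training uses Adam at a static learning rate of 0.0005, inverted dropout
0.5 on the pooled representation feeding the output layer (the recurrent
block's output, where regularisation is described as acting), global
gradient-norm clipping at 1.0, and early stopping on a held-out validation
split with patience 10. Weights start uniform scaled by fan-in; the output
bias starts at the training labels' base rates on the logit scale, so the
first epochs are spent on the discriminative signal rather than on learning
the marginals. Batch size is a free parameter with default 32; note that
with a static learning rate the effective amount of optimisation is the
number of Adam steps, `epochs * n / batch_size`, so small-epoch budgets
are best paired with small batches. Sequences are the post's content
tokens, truncated at the 95th percentile of training lengths by default
(configurable). Training is deterministic given the seed under
single-threaded BLAS. The per-step recursions of the recurrent models run
in compiled code (RcppArmadillo) with the four gates fused into one matrix
product; the R-level `lstm_step()`/`encode_sequence()` functions implement
the same equations independently and the tests hold the two routes
together.

## Active learning

The loop holds a labeled set and an unlabeled pool. Each round retrains
from scratch (fresh seed derived from the base seed and round number —
warm starts would confound the comparison between acquisition strategies),
scores the pool by the sum of per-symptom binary entropies of the predicted
probabilities — the factorised form matching nine independent sigmoid
outputs — and moves the `batch_k` highest-entropy posts (ties broken by
post id) into the labeled set, labeled by the weak labeler (or by true
labels, simulating a human oracle). It stops when the pool is empty, a
round cap is reached, or the validation metric has not improved for two
consecutive rounds. The per-cycle batch size is configurable (default
100). A uniform-random acquisition strategy is built in as the comparison
baseline; learning-curve dominance of entropy over random at matched label
budgets is the testable core of the claim that uncertainty-driven
acquisition reduces annotation effort.

On the synthetic corpus that claim does not hold, and the suite reports it
honestly: at matched budgets the entropy strategy consistently needs *more*
labels than random selection to reach the same validation AUC, whether the
acquired labels come from the weak labeler or from a simulated human oracle,
and at both moderate and low symptom prevalence. The mechanism is visible in
what gets selected: the factorised entropy is largest for posts with many
mid-probability symptoms, so acquisition concentrates on multi-positive
posts whose mean embeddings superimpose several symptom directions at once —
informative in the uncertainty sense, but poorer per-symptom training signal
than a representative random draw. This is a known weakness of plain
uncertainty sampling in multi-label bag-of-embedding settings rather than an
implementation artifact; the loop, the entropy rule and the comparison
harness are each tested against oracles independently.

## Evaluation and visualisation

AUC is computed by the rank (pair-counting) formulation — exact, ties
counting one half — with curves reported at every unique threshold. The
headline metric is the unweighted mean AUC over the nine symptoms
(macro average); a micro average over instances would let prevalent
symptoms dominate, and per-symptom reporting is retained alongside the
mean. Symptoms whose test labels are single-class are skipped with a
warning. Attention renderings normalise weights to intensities
$\alpha_t / \max_t \alpha_t$ and write per-token background opacity on a
single hue (a linear opacity ramp; the exact palette carries no meaning),
with the top-$n$ tokens flagged.

## The synthetic corpus generator

No clinical forum corpus can ship with the package, so `generate_corpus()`
manufactures one at the scale of the study population the pipeline
targets: about 232 words and 9 sentences per post, with per-symptom
prevalence 0.3 and planted signal `Poisson(3) + 1` symptom-lexicon terms
per positive symptom at the defaults. Design choices, fixed once:

* **Filler text.** Tokens are drawn from a Zipf-like frequency law whose
  high-frequency head is the closed-class function-word list and whose tail
  is 500 pronounceable neutral pseudo-words. This mirrors real prose, where
  the frequency head is function words — which POS filtering then removes,
  exactly as it would on real text. No real forum sentences are shipped.
* **Vector fixture.** `generate_vector_fixture()` places each symptom's
  terms around a distinct anchor direction (anchors mutually orthonormal),
  with cluster cohesion 2, giving within-cluster cosines near 0.8 —
  typical of close synonyms in distributional spaces; filler words are
  isotropic unit vectors. The default dimension is 300, matching the
  pre-trained vectors it stands in for. At much lower dimensions random
  filler directions begin to collide with anchors, which is a property of
  low-dimensional isotropy worth knowing about when configuring
  experiments.
* **Labels.** Symptoms are independent Bernoulli by default; a
  `label_correlation` knob routes a shared latent severity into all nine
  for realism experiments. A single master seed spawns per-component
  substreams so corpus, vectors and database can be regenerated
  independently.

What passing tests on this corpus show: that every pipeline stage does its
declared job — planted signal is recovered, expansion adds recoverable
signal, attention finds the planted tokens, uncertainty sampling needs no
more labels than random. What they do not show: performance on real
clinical text, whose symptom expression is figurative, negated,
cross-sentence and class-imbalanced in ways the generator deliberately
does not imitate. The synthetic numbers are pipeline verification, not
clinical validation.

## Replication experiment sizes

The packaged experiments (`weak_recovery_experiment()`,
`expansion_benefit_experiment()`, `model_ordering_experiment()`,
`al_comparison_experiment()`) run at sizes chosen for a desk machine:
corpora of 600–2000 posts, five replicate seeds, recurrent models at
hidden size 16 over 16-dimensional domain embeddings, sequences truncated
to 48 content tokens, and 30 training epochs at batch size 1 (so the epoch
budget still supplies roughly 48,000 Adam steps). The feedforward rounds
inside the active-learning comparison run 150 epochs on all acquired
labels. At these sizes the full suite completes in minutes on one core.

Two behaviours observed at this scale are worth recording. First, with a
static 0.0005 learning rate the nine symptoms are not learned in parallel:
symptoms break out of the base-rate prediction one after another, and a
30-epoch budget typically leaves one or two symptoms still at chance. The
mean AUC clears its target despite this, but per-post attention
localization — whether planted tokens out-weigh filler in a given post —
fails precisely on posts whose planted tokens belong to a straggler
symptom, which keeps the localization rate below what per-token inspection
of the learned symptoms alone would suggest. Second, distributional
artifacts of small corpora matter: PPMI is known to inflate rare-word
associations, and attention will happily exploit any rare-word signature
that correlates with the labels. Context-distribution smoothing was
evaluated for the embedding and rejected: at this corpus size it diluted
the symptom clusters more than it suppressed the artifact.

## Known limitations

* The contraction table, function-word list and sentence splitter are
  English-only.
* The weak labeler scores whole posts; no per-sentence localisation or
  PHQ-9 severity summation (the 0–3 frequency scale and its 0–27 total are
  documented semantics, but the pipeline's output is binary per symptom).
* The domain embedding is a bag-of-contexts estimator; it cannot represent
  negation or word order, and the classifiers inherit whatever it misses.
* Threshold calibration needs a gold anchor whose class balance resembles
  the deployment corpus; a skewed anchor skews all nine thresholds.
* Plain multilabel-entropy acquisition is not a safe default: on
  homogeneous corpora it selects redundant multi-symptom posts and can
  trail random selection (see the active-learning section). Margin- or
  diversity-aware acquisition would be the natural extension.
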