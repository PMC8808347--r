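---
title: "Methods: streaming headword trees, topic filters and tree-structured active learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streaming headword trees, topic filters and tree-structured active learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(topictree)
```

# The model

## Document representation

A document is tokenized (lowercased, non-alphanumerics stripped,
whitespace split, stopwords removed) and represented by the arithmetic
mean of the word-embedding vectors of its in-vocabulary tokens. Tokens
absent from the embedding table are dropped before any scoring; a
document with no in-vocabulary token cannot be placed in vector space and
is rejected at ingest with a warning. Repeated tokens contribute
repeatedly — both to document means and to node accumulators — because
token frequency is part of what a node summary should reflect. All
similarity is cosine.

The embedding loader reads the word2vec *text* dialect only (a header
`count dim`, then one token and `dim` floats per line, plain or gzipped).
Zero vectors are rejected at load because cosine similarity is undefined
for them. Per-node accumulators are dense over the table vocabulary, so
the loader's `vocabulary` filter (restricting the table to the corpus
vocabulary) is the intended way to use large pre-trained embeddings.

## The streaming cluster tree

Documents are streamed one by one through a binary tree. Every
clustering node a document visits updates three aggregates: a token-count
accumulator, the sum `S` of the embedding vectors of every token
occurrence, and the list of assigned document ids. Nothing else is
stored — no text, no per-document vectors — which is the streaming
property: node state is bounded by the vocabulary and the headword count,
independent of corpus size or document length.

A node is summarized by up to `k_headwords` (default 10) *headwords*,
chosen by greedy forward selection from the tokens observed at the node:
starting from the empty set, repeatedly add the token that maximizes the
cosine between the summed headword embeddings and `S`, stopping at `k`
or when no addition improves the objective. Ties at the argmax break by
higher token count, then lexicographically, which makes selection
deterministic. Greedy selection is not globally optimal in the worst
case; on accumulators of the kind the tree actually produces (a dominant
topic direction plus noise) it stays within a few percent of the
exhaustive-subset optimum, which the test suite verifies against a
brute-force oracle on small vocabularies.

Routing compares a document to the two children of a node: the child
score is the mean, over the document's token occurrences, of the cosine
between the token and its closest child headword. The mean (rather than
the sum) makes the score invariant to document length. Exact ties go to
the left child.

A leaf that has absorbed `min_docs_for_split` documents (default 50)
splits into two children, provided the clustering-node budget
`max_nodes` allows; classifier nodes and discard bins do not count
against that budget, so a 32-leaf binary tree corresponds to
`max_nodes = 63`. Fresh children need headwords before any document can
be routed, so each split seeds them with one provisional headword each:
the two observed tokens at the parent with the lowest mutual cosine —
the most dissimilar pair, encouraging divergent children. The pairwise
search is capped at the 256 most frequent observed tokens to bound the
cosine matrix. Provisional headwords are replaced at the next headword
re-selection.

## Refinement passes

After the corpus has been streamed once, it is streamed again:
accumulators and assignments reset at the start of each pass, documents
re-route under the current headwords, and every populated node re-selects
its headwords from the fresh accumulator at pass end (pass-end rather
than continuous update keeps a pass deterministic and order-robust).
Splits may occur on any pass, subject to `max_nodes`.

The loop monitors the summed headword objective across nodes. Routing
and headword selection do not optimize a single global objective, so a
pass can lower the sum slightly; the loop therefore keeps a snapshot and
rolls a non-improving pass back, stopping at a local maximum of the
summed objective — which is precisely the stopping rule the method calls
for. Termination: improvement below `convergence_tol` (default 1e-9,
an exact-arithmetic tolerance rather than a tuned one) or `max_passes`
(default 10) total passes. The recorded per-pass objective sequence is
consequently non-decreasing, and on well-separated data the loop
typically stops after two passes (the second pass confirming the first
pass's local maximum).

Because the tree is streaming, its shape depends on document order.
`repeated_build_summary()` reports the mean hierarchical F1 over builds
with shuffled orders together with a normal-approximation 95% CI, which
is the package's standard way to quote clustering quality.

## Topic filters

A topic classifier node is a binary gate: a linear-kernel SVM
(regularization `C = 1`, no feature scaling — mean-embedding features
share one scale already) on mean-embedding document vectors. Probability
calibration is a logistic (Platt) fit of the training labels on the
SVM's decision values. Fitting the calibration on training decision
values, rather than on internal cross-validation folds, keeps training
deterministic and works for the tiny seed-word training sets of the
In-Scope root; its probabilities are optimistically sharp, which is
immaterial here because filtering thresholds at 0.5 and uncertainty
sampling needs only the *ranking* of `|p - 0.5|`. On perfectly separable
data the logistic fit diverges to a steep sigmoid (harmless, same
reasons); if the decision values are degenerate (no spread), the model
falls back to the constant base rate. Documents with `p >= 0.5` are
accepted (ties to the positive side) and descend the classifier's
clustering child; the rest go to its clustering brother.

The tree root can be an "In-Scope" classifier trained from user seed
words as one-token positive pseudo-documents and stopwords as one-token
negatives (a seed word present in the stopword list is kept as a
positive). Documents it rejects land in an inspectable out-of-scope
*bin* rather than a clustering subtree: rejected-at-the-gate documents
are noise by definition, and keeping them in a flat bin makes the
decision reviewable without spending tree budget on them.

New classifiers insert at the top of the region they were discovered in:
under the nearest ancestor classifier (or above the clustering root),
taking over its accept edge, with a fresh empty clustering child for
accepted documents and the displaced subtree as the brother. Several
classifiers at one level form a cascade — a document rejected by the
newest filter is tested by the next, and only documents rejected by all
of them reach the shared clustering brother. A classifier attached under
another classifier's accept side is a subtopic. A classifier with an
empty training class is inactive and passes everything to its brother
until it becomes trainable.

Feedback events (`doc_id`, `classifier`, `positive`/`negative`) move a
document into the named training set and out of the opposite one, so the
sets stay disjoint and events are idempotent; affected classifiers are
retrained and the corpus re-streamed. Optional sibling augmentation
enlarges a classifier's negatives with the positives of its same-level
siblings (excluding its own positives) — the most conservative reading
of "use the surrounding classifiers' instances", and opt-in for that
reason.

## Tree-structured active learning

`D_max` is the tree depth with the most clustering nodes (ties toward
the deeper level: more, smaller nodes spread candidates better). The
first batch draws round-robin over the `D_max` nodes, one uniformly
random unlabeled document per node per cycle, skipping exhausted nodes,
until `batch_size` (default 50) documents are collected. Once a model
exists, batches split evenly between the positive tree (under the
classifier) and the negative tree (under its brother) — `batch_size/2`
each, the positive tree taking the extra draw for odd sizes. Within a
subtree the selection is again round-robin over its own `D_max` nodes,
but each node now contributes its most *uncertain* unlabeled document,
the one with predicted probability closest to 0.5. If one subtree's
widest-level pool exhausts, the remainder comes from the other.
"Chosen consecutively" is implemented as strict node cycling, one pick
per node per cycle.

The simulation harness evaluates strategies one class at a time,
one-vs-rest: the corpus splits into a labeling pool and a held-out test
set (defaults 1000/1000), batches are selected, gold verdicts revealed,
the classifier retrained after every batch, and — for the tree strategy
— the positive/negative trees rebuilt from the current model before the
next selection. Test metrics are recorded at the 50/100/150/200-label
checkpoints and weighted across classes by test support. The baselines:
`random` (uniform without replacement) and `pool_uncertainty` (global
`|p - 0.5|` argmin, no tree). Baselines start from a random first batch
and the tree strategy from the round-robin batch, since no model exists
yet; until a batch contains both verdicts no model can be trained and
the test prediction is all-negative. With a single-node tree the tree
strategy degenerates to pool uncertainty sampling, which the tests use
as an equivalence oracle.

The trees the strategy rebuilds after every batch use a deliberately
small configuration (31 nodes, split threshold 25, 2 passes): selection
only needs a well-spread widest level, and rebuild cost is paid once per
batch per class.

## Evaluating hierarchies

The hierarchical F1 treats membership transitively: a document belongs
to every node on its path, so internal nodes are candidate clusters too.
Per gold class, the score is the best F1 over all nodes; the overall
score is the class-support-weighted mean. No restriction to leaves or to
a fixed number of candidate nodes is applied — leaf-count settings (32
or 64) are clustering configurations, not metric parameters. Documents
without a gold label are ignored by the metric. Per-class "accuracy" in
the classification reports is one-vs-rest; zero-division cases score 0
and carry a flag.

# Synthetic benchmarks

The generators produce the two study conditions the package is tested
under; both are deterministic under their seed.

**Embedding geometry.** One centroid per topic on a sphere of radius
`separation/sqrt(2)` (random directions in high dimension are nearly
orthogonal, so the expected centroid distance is `separation`); topic
tokens are the centroid plus isotropic Gaussian noise of unit expected
norm, making `separation` the centroid distance in units of within-topic
token spread. Shared noise tokens scatter around the centroid mean.
This is the simplest geometry consistent with the assumption that
semantically similar words are close in embedding space.

**Clustering benchmark** (`clustering_benchmark_spec()`): 5 topics,
separation 5, dimension 50, 2000 documents of 30 tokens, 5% noise rate
— well-separated topics that a 32-leaf tree should recover, quoted as
the mean hierarchical F1 over 10 random document orders.

**Active-learning benchmark** (`al_benchmark_spec()`): the regime where
instance selection matters. A document vector is a mean of
`doc_length` tokens, so its class-conditional spread along a linear
discriminant is about `1/sqrt(embedding_dim * doc_length)`; classes
overlap only when the effective centroid distance
`(1 - noise_token_rate) * separation` is comparable to that spread. The
benchmark uses separation 0.15, 10-token documents, 30% noise and the
skewed mixture (0.35, 0.25, 0.18, 0.14, 0.08) — a few large classes and
a rare one, mirroring typical topic-code imbalance — placing the
effective gap at roughly 2.3 spread units so that scores climb across
the 50–200-label checkpoints instead of saturating. 2000 documents
support the 1000/1000 pool/test split; the comparison runs over 10
simulation seeds.

**What the generators do not emulate:** real language (tokens are
symbols, not words), polysemy and anisotropy of trained embeddings,
multi-label documents, document-length variation, and topic hierarchies
(gold classes are flat). Passing benchmarks therefore demonstrate the
correctness and the qualitative behavior of the algorithms under their
stated geometric assumptions, not performance on any particular real
corpus.

# Numerical and degenerate-input choices

- Determinism everywhere: routing ties go left; headword ties break by
  count then token; uncertainty ties break by document id; every random
  draw takes an explicit seed and runs in a private RNG stream.
- A leaf with fewer than two distinct observed tokens cannot seed two
  children and simply does not split.
- `hierarchical_f1` errors on labeled-but-unassigned documents rather
  than silently scoring them as misses.
- Identical positive and negative training examples make the SVM
  degenerate; training either errors or yields the constant base-rate
  model, and both are acceptable terminal states for a filter.
- Serialization writes full-precision doubles; identical builds are
  byte-identical, which the acceptance checks assert.

# Known limitations

- The greedy headword optimality guarantee is empirical and
  geometry-dependent: on adversarial isotropic token sets greedy can
  fall below 95% of the exhaustive optimum; the tests state the bound
  for accumulators drawn from the package's embedding geometry.
- Platt calibration on training decision values yields over-confident
  probabilities; anything needing honestly calibrated probabilities
  (rather than thresholds and rankings) should recalibrate on held-out
  data.
- Dense per-node accumulators assume the embedding table is restricted
  to the corpus vocabulary; with an unfiltered 100k-token table, memory
  grows with `max_nodes * vocab`.
- The cascade insertion order makes same-level classifiers
  order-dependent: the newest classifier sees every document first.
- Binary splits only; no merge moves; no distributed execution.
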