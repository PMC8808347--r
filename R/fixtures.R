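#' Specification for synthetic topic-structured fixtures
#'
#' Describes a corpus of documents drawn from topic-specific vocabularies
#' whose word embeddings form Gaussian clusters: one centroid per topic
#' on a scaled sphere, token vectors scattered around it with unit total
#' spread, so `separation` is the centroid distance in units of
#' within-topic spread.  A shared pool of noise tokens sits near the
#' centroid mean, emulating topic-neutral vocabulary.
#'
#' @param n_topics Number of topics (default 5).
#' @param vocab_per_topic Tokens per topic vocabulary (default 40).
#' @param embedding_dim Embedding dimension (default 50).
#' @param separation Centroid distance relative to within-topic spread
#'   (default 5).
#' @param n_docs Number of documents (default 2000).
#' @param doc_length Tokens per document (default 30).
#' @param topic_mixture Topic proportions, summing to 1 (default equal).
#' @param noise_token_rate Probability that a token is drawn from the
#'   shared noise pool instead of the topic vocabulary (default 0.05).
#' @param n_noise_tokens Size of the shared noise vocabulary (default 20).
#' @param seed Generator seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_topics = 5L, vocab_per_topic = 40L,
                         embedding_dim = 50L, separation = 5,
                         n_docs = 2000L, doc_length = 30L,
                         topic_mixture = NULL, noise_token_rate = 0.05,
                         n_noise_tokens = 20L, seed = 1L) {
  if (is.null(topic_mixture)) topic_mixture <- rep(1 / n_topics, n_topics)
  stopifnot(n_topics >= 1, vocab_per_topic >= 1, embedding_dim >= 2,
            separation >= 0, n_docs >= 1, doc_length >= 1,
            length(topic_mixture) == n_topics,
            noise_token_rate >= 0, noise_token_rate <= 1)
  if (abs(sum(topic_mixture) - 1) > 1e-9) {
    stop("topic_mixture must sum to 1")
  }
  structure(list(n_topics = as.integer(n_topics),
                 vocab_per_topic = as.integer(vocab_per_topic),
                 embedding_dim = as.integer(embedding_dim),
                 separation = separation, n_docs = as.integer(n_docs),
                 doc_length = as.integer(doc_length),
                 topic_mixture = topic_mixture,
                 noise_token_rate = noise_token_rate,
                 n_noise_tokens = as.integer(n_noise_tokens),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate synthetic topic-clustered word embeddings
#'
#' Per topic, a centroid is drawn uniformly on a sphere of radius
#' `separation / sqrt(2)` (so the expected centroid distance is about
#' `separation`); each topic token is the centroid plus isotropic
#' Gaussian noise scaled to unit expected norm.  Noise tokens scatter
#' around the mean of the centroids.  Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return An [embedding_table()] with tokens `t<k>w<j>` (topic `k`) and
#'   `noisew<j>`.
#' @export
make_embeddings <- function(spec) {
  d <- spec$embedding_dim
  if (d < 2) stop("embedding_dim must be at least 2")
  with_seed(spec$seed, {
    cent <- matrix(rnorm(spec$n_topics * d), spec$n_topics, d)
    cent <- cent / sqrt(rowSums(cent^2)) * spec$separation / sqrt(2)
    rows <- list()
    for (k in seq_len(spec$n_topics)) {
      tok <- matrix(rnorm(spec$vocab_per_topic * d, sd = 1 / sqrt(d)),
                    spec$vocab_per_topic, d)
      tok <- sweep(tok, 2, cent[k, ], `+`)
      rownames(tok) <- sprintf("t%dw%02d", k, seq_len(spec$vocab_per_topic))
      rows[[k]] <- tok
    }
    noise <- matrix(rnorm(spec$n_noise_tokens * d, sd = 1 / sqrt(d)),
                    spec$n_noise_tokens, d)
    noise <- sweep(noise, 2, colMeans(cent), `+`)
    rownames(noise) <- sprintf("noisew%02d", seq_len(spec$n_noise_tokens))
    embedding_table(do.call(rbind, c(rows, list(noise))))
  })
}

#' Generate a labeled synthetic corpus
#'
#' Each document samples a topic from `topic_mixture`, then `doc_length`
#' tokens uniformly from that topic's vocabulary, each replaced by a
#' shared noise token with probability `noise_token_rate`.  The gold
#' label is the topic id.  Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A `corpus` data frame (id, text, label) that round-trips
#'   through [write_corpus()] / [read_corpus()] and tokenizes onto the
#'   vocabulary of [make_embeddings()].
#' @export
make_corpus <- function(spec) {
  if (spec$doc_length < 1) stop("doc_length must be positive")
  with_seed(spec$seed + 1L, {
    topics <- sample.int(spec$n_topics, spec$n_docs, replace = TRUE,
                         prob = spec$topic_mixture)
    texts <- vapply(seq_len(spec$n_docs), function(i) {
      k <- topics[i]
      toks <- sprintf("t%dw%02d", k,
                      sample.int(spec$vocab_per_topic, spec$doc_length,
                                 replace = TRUE))
      is_noise <- stats::runif(spec$doc_length) < spec$noise_token_rate
      if (any(is_noise)) {
        toks[is_noise] <- sprintf("noisew%02d",
                                  sample.int(spec$n_noise_tokens,
                                             sum(is_noise), replace = TRUE))
      }
      paste(toks, collapse = " ")
    }, character(1))
    out <- data.frame(id = sprintf("doc%05d", seq_len(spec$n_docs)),
                      text = texts,
                      label = sprintf("T%d", topics),
                      stringsAsFactors = FALSE)
    class(out) <- c("corpus", class(out))
    out
  })
}

#' Benchmark conditions for clustering quality
#'
#' Five well-separated topics (separation 5, dimension 50), 2000
#' documents of 30 tokens with a 5% noise-token rate: the regime where a
#' 32-leaf tree is expected to recover the topic structure.
#'
#' @param seed Generator seed.
#' @return A [fixture_spec()].
#' @export
clustering_benchmark_spec <- function(seed = 1L) {
  fixture_spec(n_topics = 5L, vocab_per_topic = 40L, embedding_dim = 50L,
               separation = 5, n_docs = 2000L, doc_length = 30L,
               noise_token_rate = 0.05, seed = seed)
}

#' Benchmark conditions for active-learning comparison
#'
#' Emulates the features of a real literature corpus that make instance
#' selection matter: genuinely overlapping topics and skewed class sizes
#' (a few large classes and a rare one, mirroring typical topic-code
#' imbalance).  Because a document vector is the *mean* of its token
#' vectors, the class-conditional spread along a linear discriminant
#' shrinks like `1/sqrt(embedding_dim * doc_length)`; classes only
#' overlap when the effective centroid distance
#' `(1 - noise_token_rate) * separation` is comparable to that spread.
#' Short documents (10 tokens), separation 0.15 and a 30% shared-noise
#' rate put the benchmark in that regime (an effective gap of roughly
#' 2.3 spread units), where classifier scores climb over the
#' checkpoints instead of saturating immediately.  2000
#' documents, enough for a 1000/1000 pool/test split.
#'
#' @param seed Generator seed.
#' @return A [fixture_spec()].
#' @export
al_benchmark_spec <- function(seed = 1L) {
  fixture_spec(n_topics = 5L, vocab_per_topic = 40L, embedding_dim = 50L,
               separation = 0.15, n_docs = 2000L, doc_length = 10L,
               topic_mixture = c(0.35, 0.25, 0.18, 0.14, 0.08),
               noise_token_rate = 0.3, seed = seed)
}

#' Random labeled tree assignment for metric testing
#'
#' Generates a random tree topology (each new node attaches to a random
#' existing node), assigns every document to a random leaf, labels it
#' with a random class, and returns the transitive per-node document
#' sets -- the oracle input shape for [hierarchical_f1()].
#'
#' @param n_docs,n_nodes,n_classes Sizes.
#' @param seed Integer seed.
#' @return List with `node_docs` (per-node character id vectors, doc ids
#'   propagated to all ancestors), `labels` (named by doc id), and
#'   `parent` (the topology).
#' @export
make_labeled_tree <- function(n_docs, n_nodes, n_classes, seed = 1L) {
  stopifnot(n_nodes >= 1, n_docs >= 1, n_classes >= 1)
  with_seed(seed, {
    parent <- integer(n_nodes)
    if (n_nodes > 1) {
      for (i in 2:n_nodes) parent[i] <- sample.int(i - 1L, 1L)
    }
    is_leaf <- !(seq_len(n_nodes) %in% parent)
    leaves <- which(is_leaf)
    ids <- sprintf("d%04d", seq_len(n_docs))
    at <- leaves[sample.int(length(leaves), n_docs, replace = TRUE)]
    labels <- sprintf("C%d", sample.int(n_classes, n_docs, replace = TRUE))
    names(labels) <- ids
    node_docs <- vector("list", n_nodes)
    for (i in seq_len(n_docs)) {
      nd <- at[i]
      while (nd != 0L) {
        node_docs[[nd]] <- c(node_docs[[nd]], ids[i])
        nd <- parent[nd]
      }
    }
    node_docs <- lapply(node_docs, function(x) if (is.null(x)) character(0)
                                               else x)
    list(node_docs = node_docs, labels = labels, parent = parent)
  })
}
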