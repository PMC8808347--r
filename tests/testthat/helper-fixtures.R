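# Shared fixtures, built once per test run and cached.

.tt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tt_cache[[key]])) .tt_cache[[key]] <- force(expr)
  .tt_cache[[key]]
}

# tiny hand-built embedding table in 2-D / 3-D for closed-form checks
toy_table_2d <- function() {
  embedding_table(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1),
                        d = c(2, 2), e = c(-1, 0)))
}

# small well-separated 3-topic world for structural tests
small_world <- function() {
  cached("small_world", {
    spec <- fixture_spec(n_topics = 3L, vocab_per_topic = 12L,
                         embedding_dim = 12L, separation = 6,
                         n_docs = 400L, doc_length = 8L,
                         noise_token_rate = 0.05, seed = 7L)
    table <- make_embeddings(spec)
    corpus <- make_corpus(spec)
    docs <- vectorize_corpus(corpus, table)
    list(spec = spec, table = table, corpus = corpus, docs = docs)
  })
}

small_tree <- function() {
  cached("small_tree", {
    w <- small_world()
    build_tree(w$docs, w$table,
               tree_config(min_docs_for_split = 30L, max_nodes = 15L,
                           max_passes = 5L))
  })
}

# the clustering benchmark (5 separated topics, 2000 docs)
bench_world <- function() {
  cached("bench_world", {
    spec <- clustering_benchmark_spec(seed = 1L)
    table <- make_embeddings(spec)
    docs <- vectorize_corpus(make_corpus(spec), table)
    list(spec = spec, table = table, docs = docs)
  })
}

# the overlapping, imbalanced active-learning benchmark
al_world <- function() {
  cached("al_world", {
    spec <- al_benchmark_spec(seed = 1L)
    table <- make_embeddings(spec)
    docs <- vectorize_corpus(make_corpus(spec), table)
    list(spec = spec, table = table, docs = docs)
  })
}

# independent brute-force oracle for the hierarchical F1:
# plain nested loops over every (class, node) pair with set arithmetic
oracle_hierarchical_f1 <- function(node_docs, labels) {
  classes <- sort(unique(as.character(labels)))
  total <- 0
  for (cl in classes) {
    cls_ids <- names(labels)[labels == cl]
    best <- 0
    for (nd in node_docs) {
      nd <- nd[nd %in% names(labels)]
      inter <- length(intersect(cls_ids, nd))
      p <- if (length(nd)) inter / length(nd) else 0
      r <- inter / length(cls_ids)
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      if (f > best) best <- f
    }
    total <- total + best * length(cls_ids)
  }
  total / length(labels)
}

# exhaustive-subset optimum of the headword objective for small vocabularies
oracle_best_headword_set <- function(vectors, counts, S, k) {
  n <- nrow(vectors)
  best <- -Inf
  for (size in seq_len(k)) {
    combs <- utils::combn(n, size)
    for (j in seq_len(ncol(combs))) {
      h <- colSums(vectors[combs[, j], , drop = FALSE])
      if (sum(h^2) == 0) next
      v <- sum(h * S) / (sqrt(sum(h^2)) * sqrt(sum(S^2)))
      if (v > best) best <- v
    }
  }
  best
}

# random linearly separable two-cloud problem
separable_clouds <- function(n = 20, d = 5, gap = 6, seed = 42) {
  set.seed(seed)
  pos <- matrix(rnorm(n * d), n, d); pos[, 1] <- pos[, 1] + gap / 2
  neg <- matrix(rnorm(n * d), n, d); neg[, 1] <- neg[, 1] - gap / 2
  list(pos = pos, neg = neg)
}
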