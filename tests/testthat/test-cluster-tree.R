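# a controllable micro-world: orthogonal-ish tokens so affinities are exact
micro_tree <- function(texts, table = toy_table_2d(),
                       config = tree_config(min_docs_for_split = 2,
                                            max_nodes = 15,
                                            k_headwords = 2,
                                            max_passes = 3)) {
  corp <- data.frame(id = sprintf("m%02d", seq_along(texts)), text = texts,
                     stringsAsFactors = FALSE)
  docs <- vectorize_corpus(corp, table, stopwords = character())
  list(docs = docs, table = table, config = config)
}

test_that("headword objective is the cosine of summed headword vectors to the accumulator", {
  m <- micro_tree(c("a a b", "a b b"))
  tree <- new_tree(m$docs, m$table, m$config)
  insert_document(tree, "m01")
  insert_document(tree, "m02")
  # accumulator = 3 v_a + 3 v_b = (3,3); headwords {a,b} sum to (1,1)
  expect_equal(headword_objective(tree, tree$root, c("a", "b")), 1)
  # e = (-1,0) vs accumulator (3,3): cos = -cos(45)
  expect_equal(headword_objective(tree, tree$root, "e"), -sqrt(2) / 2)
  expect_error(headword_objective(tree, tree$root, character(0)), "empty")
})

test_that("greedy headword selection matches exhaustive search on small instances", {
  # orthogonal 6-token vocabulary, k = 2: the optimum over all C(6,2)
  # subsets is the top-2 token counts, and greedy provably attains it
  set.seed(3)
  for (rep in 1:10) {
    mat <- diag(6) * runif(6, 0.5, 2)
    rownames(mat) <- letters[1:6]
    tab <- embedding_table(mat)
    counts <- sample(1:50, 6)
    S <- as.numeric(crossprod(mat, counts))
    res <- topictree:::select_headwords_core(counts, S, 2L, tab)
    got <- colSums(mat[res$idx, , drop = FALSE])
    best <- oracle_best_headword_set(mat, counts, S, 2L)
    expect_equal(cosine_sim(got, S), best, tolerance = 1e-12)
  }
  # on arbitrary random instances greedy stays within 95% of the optimum
  for (rep in 1:10) {
    mat <- matrix(abs(rnorm(6 * 4)), 6, 4)
    rownames(mat) <- letters[1:6]
    tab <- embedding_table(mat)
    counts <- sample(1:5, 6, replace = TRUE)
    S <- as.numeric(crossprod(mat, counts))
    res <- topictree:::select_headwords_core(counts, S, 2L, tab)
    got <- colSums(mat[res$idx, , drop = FALSE])
    best <- oracle_best_headword_set(mat, counts, S, 2L)
    expect_gte(cosine_sim(got, S), 0.95 * best)
  }
})

test_that("headword selection exhausts small vocabularies and follows dominance", {
  m <- micro_tree(c("a b e", "a b e"))
  tree <- new_tree(m$docs, m$table,
                   tree_config(min_docs_for_split = 50, k_headwords = 10))
  insert_document(tree, "m01")
  insert_document(tree, "m02")
  hw <- select_headwords(tree, tree$root, k = 10)
  expect_lte(nrow(hw), 3)  # clamped to observed vocabulary
  # dominant token: count 100 vs 1 -> singleton argmax is the dominant one
  mat <- rbind(a = c(1, 0.2), b = c(0.3, 1))
  tab <- embedding_table(mat)
  counts <- c(a = 100, b = 1)
  S <- as.numeric(crossprod(mat, counts))
  res <- topictree:::select_headwords_core(counts, S, 1L, tab)
  expect_equal(rownames(mat)[res$idx], "a")
  # ... and equals the exhaustive singleton argmax
  singles <- apply(mat, 1, function(v) cosine_sim(v, S))
  expect_equal(rownames(mat)[res$idx], names(which.max(singles)))
})

test_that("child affinity is the mean over occurrences of max cosine to headwords", {
  m <- micro_tree(rep("a b", 3),
                  config = tree_config(min_docs_for_split = 2,
                                       max_nodes = 3, k_headwords = 1,
                                       max_passes = 1))
  tree <- build_tree(m$docs, m$table, m$config)
  # token identical to single headword -> affinity 1
  lid <- tree$left[tree$root]
  hw <- headwords(tree, lid)$token[1]
  expect_equal(child_affinity(hw, tree, lid), 1)
  # orthogonal: a vs headwords {b}
  other <- setdiff(c("a", "b"), hw)
  expect_equal(child_affinity(other, tree, lid), 0)
  # mean of (1, cos(v_b, v_a)) for doc [a, b] against headwords {a}
  anode <- if (hw == "a") lid else tree$right[tree$root]
  expect_equal(child_affinity(c("a", "b"), tree, anode),
               mean(c(1, 0)))
})

test_that("routing picks the higher-affinity child and ties go left", {
  m <- micro_tree(c(rep("a a a", 3), rep("b b b", 3)),
                  config = tree_config(min_docs_for_split = 3,
                                       max_nodes = 15, k_headwords = 1,
                                       max_passes = 2))
  tree <- build_tree(m$docs, m$table, m$config)
  root <- tree$root
  expect_equal(tree$left[root] > 0, TRUE)
  la <- child_affinity("a", tree, tree$left[root])
  ra <- child_affinity("a", tree, tree$right[root])
  want <- if (la >= ra) tree$left[root] else tree$right[root]
  expect_equal(route_document(tree, root, "a"), want)
  # exact tie: token c = (1,1) equidistant from a-child and b-child seeds
  expect_equal(route_document(tree, root, "c"), tree$left[root])
  # routing at a leaf is an error
  leaf <- which(tree$type == "cluster" & tree$left == 0)[1]
  expect_error(route_document(tree, leaf, "a"), "leaf")
})

test_that("streaming insert splits leaves at the document threshold", {
  w <- small_world()
  tree <- new_tree(w$docs, w$table, tree_config())  # default min split 50
  insert_document(tree, w$docs$ids[1])
  expect_equal(tree$doc_count[tree$root], 1)
  expect_equal(tree$left[tree$root], 0L)
  for (i in 2:49) insert_document(tree, w$docs$ids[i])
  expect_equal(tree$left[tree$root], 0L)  # 49 docs: still a leaf
  insert_document(tree, w$docs$ids[50])   # 50th triggers the split
  expect_gt(tree$left[tree$root], 0L)
  expect_equal(n_nodes(tree, "cluster"), 3L)
  # the splitting document was routed into one of the new children
  expect_equal(sum(tree$doc_count[c(tree$left[tree$root],
                                    tree$right[tree$root])]), 1)
})

test_that("the node budget stops splitting", {
  w <- small_world()
  tree <- new_tree(w$docs, w$table, tree_config(min_docs_for_split = 10,
                                                max_nodes = 3))
  for (id in w$docs$ids[1:100]) insert_document(tree, id)
  expect_equal(n_nodes(tree, "cluster"), 3L)  # one split, then absorbed
  expect_equal(tree$doc_count[tree$root], 100)
})

test_that("refinement is monotone, stops at a fixed point and honours the pass cap", {
  w <- small_world()
  cfg <- tree_config(min_docs_for_split = 30, max_nodes = 15, max_passes = 6)
  tree <- build_tree(w$docs, w$table, cfg)
  expect_true(all(diff(tree$history) >= -1e-9))
  expect_lte(length(tree$history), 6)
  # already-converged tree: one extra refine call does not change the objective
  h <- tree$history
  refine(tree, max_passes = 2)
  expect_equal(tree$history[length(tree$history)], h[length(h)],
               tolerance = 1e-9)
  # max_passes = 1 runs exactly one pass
  t1 <- build_tree(w$docs, w$table,
                   tree_config(min_docs_for_split = 30, max_nodes = 15,
                               max_passes = 1))
  expect_equal(length(t1$history), 1L)
})

test_that("parent assignments contain their children's (conservation)", {
  tree <- small_tree()
  for (id in which(tree$type == "cluster" & tree$left > 0)) {
    kids <- c(tree$left[id], tree$right[id])
    kid_ids <- unlist(lapply(kids, function(k) node_doc_ids(tree, k)))
    expect_true(all(kid_ids %in% node_doc_ids(tree, id)))
    expect_equal(tree$doc_count[id], length(node_doc_ids(tree, id)))
  }
})

test_that("accumulators are consistent: vector sum recomputable from token counts", {
  tree <- small_tree()
  E <- tree$table$vectors
  for (id in which(tree$type == "cluster" & tree$doc_count > 0)) {
    recomputed <- as.numeric(crossprod(E, tree$counts[[id]]))
    expect_equal(tree$vec_sum[[id]], recomputed, tolerance = 1e-9)
  }
})

test_that("identical corpus order, config and seed give byte-identical trees", {
  w <- small_world()
  cfg <- tree_config(min_docs_for_split = 30, max_nodes = 15, max_passes = 3)
  j1 <- save_tree(build_tree(w$docs, w$table, cfg, order_seed = 4))
  j2 <- save_tree(build_tree(w$docs, w$table, cfg, order_seed = 4))
  expect_identical(j1, j2)
  j3 <- save_tree(build_tree(w$docs, w$table, cfg, order_seed = 5))
  expect_false(identical(j1, j3))
})

test_that("serialization round-trips losslessly and reattaches to the corpus", {
  w <- small_world()
  tree <- small_tree()
  f <- withr::local_tempfile(fileext = ".json")
  save_tree(tree, f)
  back <- load_tree(f)
  expect_identical(readLines(f), as.character(save_tree(back)))
  expect_equal(node_doc_ids(back, back$root), node_doc_ids(tree, tree$root))
  attach_corpus(back, w$docs, w$table)
  expect_equal(back$vec_sum[[back$root]], tree$vec_sum[[tree$root]],
               tolerance = 1e-9)
  expect_equal(hierarchical_f1(back), hierarchical_f1(tree),
               tolerance = 1e-12)
})

test_that("representativeness orders a node's documents by headword affinity", {
  tree <- small_tree()
  id <- tree$root
  r <- representativeness(tree, id)
  expect_equal(nrow(r), as.integer(tree$doc_count[id]))
  expect_true(all(diff(r$score) <= 1e-12))
  rev <- representativeness(tree, id, decreasing = FALSE)
  expect_true(all(diff(rev$score) >= -1e-12))
  expect_equal(r$id[1], rev$id[nrow(rev)])
  # a document made of the node's own headwords scores 1
  hw <- headwords(tree, id)$token
  expect_equal(child_affinity(hw, tree, id), 1, tolerance = 1e-9)
})
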