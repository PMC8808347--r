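test_that("linearly separable clouds are fit perfectly and calibrated sanely", {
  cl <- separable_clouds()
  m <- train_margin_classifier(cl$pos, cl$neg)
  expect_true(all(predict_margin(m, cl$pos) > 0.5))
  expect_true(all(predict_margin(m, cl$neg) < 0.5))
  # retraining on the same inputs gives identical predictions
  m2 <- train_margin_classifier(cl$pos, cl$neg)
  expect_identical(predict_margin(m, cl$pos), predict_margin(m2, cl$pos))
})

test_that("training rejects empty classes and degenerate inputs stay harmless", {
  cl <- separable_clouds(n = 5)
  expect_error(train_margin_classifier(cl$pos[0, , drop = FALSE], cl$neg),
               "both classes")
  # identical single positive and negative: no usable margin
  res <- tryCatch(train_margin_classifier(matrix(c(1, 1), 1),
                                          matrix(c(1, 1), 1)),
                  error = function(e) "degenerate")
  if (!identical(res, "degenerate")) {
    expect_equal(predict_margin(res, c(1, 1)), 0.5, tolerance = 1e-6)
  } else {
    succeed()
  }
})

test_that("prediction validates its inputs", {
  cl <- separable_clouds(n = 8, d = 3)
  m <- train_margin_classifier(cl$pos, cl$neg)
  expect_error(predict_margin(m, c(1, 2)), "dimension mismatch")
  expect_error(predict_margin(list(), c(1, 2, 3)), "untrained")
  p <- predict_margin(m, rbind(cl$pos, cl$neg))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("filter_route applies the 0.5 threshold with ties to the positive side", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  t1 <- which(w$docs$labels == "T1")
  t2 <- which(w$docs$labels != "T1")
  cid <- attach_classifier(tree, tree$root, "topic1",
                           positive_ids = w$docs$ids[t1[1:10]],
                           negative_ids = w$docs$ids[t2[1:10]])
  rebuild_tree(tree)
  expect_equal(filter_route(tree, cid, w$docs$ids[t1[11]]), "accepted")
  expect_equal(filter_route(tree, cid, w$docs$ids[t2[11]]), "rejected")
  # ties accept: a constant-probability 0.5 model
  const <- structure(list(w = c(0, 0), b = 0, platt = c(NA, NA), base = 0.5,
                          cost = 1, dim = 2), class = "margin_model")
  tree$cls_model[[cid]] <- const
  expect_equal(filter_route(tree, cid, c(1, 1)), "accepted")
})

test_that("the In-Scope root trains from seed words and partitions the corpus", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  seeds <- rownames(w$table$vectors)[1:4]   # topic-1 vocabulary as seeds
  stop_plus <- c(seeds[1], "noisew01", "noisew02")  # overlap is removed
  make_in_scope(tree, c(seeds, "notaword"), stopwords = stop_plus) |>
    expect_warning("notaword")
  cid <- which(!is.na(tree$cls_name) & tree$cls_name == "in_scope")
  expect_false(seeds[1] %in% tree$cls_neg[[cid]])
  expect_true(seeds[1] %in% tree$cls_pos[[cid]])
  # partition invariant: accepted subtree + bin cover every document once
  bin <- which(tree$type == "bin")
  acc_root <- tree$left[cid]
  accepted <- node_doc_ids(tree, acc_root)
  binned <- node_doc_ids(tree, bin)
  expect_equal(sort(c(accepted, binned)), sort(w$docs$ids))
  expect_length(intersect(accepted, binned), 0)
  fresh <- new_tree(w$docs, w$table, tree_config())
  expect_error(suppressWarnings(make_in_scope(fresh, "zzznotavocab")),
               "out of vocabulary")
})

test_that("tree surgery inserts classifiers with a fresh child and a brother", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  old_root <- tree$root
  t1 <- w$docs$ids[w$docs$labels == "T1"]
  t2 <- w$docs$ids[w$docs$labels == "T2"]
  rest <- setdiff(w$docs$ids, c(t1, t2))
  c1 <- attach_classifier(tree, old_root, "alpha",
                          positive_ids = t1[1:8], negative_ids = rest[1:8])
  expect_equal(tree$root, c1)
  expect_equal(tree$right[c1], old_root)        # displaced subtree = brother
  expect_equal(tree$type[tree$left[c1]], "cluster")  # fresh empty child
  expect_error(attach_classifier(tree, old_root, "alpha"), "collision")
  # a second topic chains at the top: rejected documents cascade to the
  # previous classifier, and only then to the clustering brother
  c2 <- attach_classifier(tree, old_root, "beta",
                          positive_ids = t2[1:8], negative_ids = t1[1:8])
  expect_equal(tree$root, c2)
  expect_equal(tree$right[c2], c1)
  expect_equal(tree$right[c1], old_root)
  # chained classifiers share an owner (they are siblings, not subtopics)
  expect_equal(topictree:::classifier_owner(tree, c1),
               topictree:::classifier_owner(tree, c2))
  # a subtopic under beta's accepted child is a classifier under a classifier
  rebuild_tree(tree)
  sub <- attach_classifier(tree, tree$left[c2], "beta-sub",
                           positive_ids = t1[9:12],
                           negative_ids = rest[9:12])
  expect_equal(tree$parent[sub], c2)
  expect_equal(topictree:::classifier_owner(tree, sub), c2)
  # inactive classifier (no training data) passes everything to the brother
  tree2 <- build_tree(w$docs, w$table,
                      tree_config(min_docs_for_split = 30, max_nodes = 7,
                                  max_passes = 2))
  c0 <- attach_classifier(tree2, tree2$root, "empty")
  rebuild_tree(tree2)
  expect_equal(tree2$doc_count[tree2$left[c0]], 0)
  expect_equal(tree2$doc_count[tree2$right[c0]], w$docs$n)
})

test_that("after a rebuild every document under a classifier's child is accepted by it", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  target <- tree$root  # the clustering root, before any surgery
  for (topic in c("T1", "T2", "T3")) {
    pos <- w$docs$ids[w$docs$labels == topic]
    neg <- w$docs$ids[w$docs$labels != topic]
    attach_classifier(tree, target, paste0("cls-", topic),
                      positive_ids = pos[1:10], negative_ids = neg[1:10])
  }
  rebuild_tree(tree)
  for (cid in which(tree$type == "classifier")) {
    m <- tree$cls_model[[cid]]
    under <- node_doc_ids(tree, tree$left[cid])
    if (!length(under)) next
    p <- predict_margin(m, w$docs$vectors[match(under, w$docs$ids), ,
                                          drop = FALSE])
    expect_true(all(p >= 0.5))
    # and the partition is exact: child + brother hold disjoint sets
    over <- node_doc_ids(tree, tree$right[cid])
    expect_length(intersect(under, over), 0)
  }
})

test_that("feedback events are exclusive, idempotent and flip separable margins", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  t1 <- w$docs$ids[w$docs$labels == "T1"]
  t2 <- w$docs$ids[w$docs$labels == "T2"]
  # poison one training positive with a wrong-topic document
  attach_classifier(tree, tree$root, "alpha",
                    positive_ids = c(t1[1:6], t2[1]),
                    negative_ids = t2[2:7])
  rebuild_tree(tree)
  ev <- data.frame(doc_id = t2[1], classifier = "alpha",
                   verdict = "negative", stringsAsFactors = FALSE)
  apply_feedback(tree, ev)
  cid <- which(!is.na(tree$cls_name) & tree$cls_name == "alpha")
  expect_false(t2[1] %in% tree$cls_pos[[cid]])
  expect_true(t2[1] %in% tree$cls_neg[[cid]])
  # the corrected document is now rejected by the retrained filter
  expect_equal(filter_route(tree, cid, t2[1]), "rejected")
  expect_false(t2[1] %in% node_doc_ids(tree, tree$left[cid]))
  # idempotence
  before <- save_tree(tree)
  apply_feedback(tree, ev)
  expect_identical(save_tree(tree), before)
  expect_error(apply_feedback(tree, transform(ev, classifier = "nope")),
               "unknown classifier")
})

test_that("sibling augmentation adds sibling positives as extra negatives", {
  w <- small_world()
  tree <- build_tree(w$docs, w$table,
                     tree_config(min_docs_for_split = 30, max_nodes = 7,
                                 max_passes = 2))
  t1 <- w$docs$ids[w$docs$labels == "T1"]
  t2 <- w$docs$ids[w$docs$labels == "T2"]
  shared <- t1[1]
  target <- tree$root
  attach_classifier(tree, target, "A",
                    positive_ids = t1[1:5], negative_ids = t2[6:8])
  attach_classifier(tree, target, "B",
                    positive_ids = c(t2[1:5], shared),
                    negative_ids = t1[6:8])
  aug <- augment_training(tree, "A")
  expect_true(all(t2[1:5] %in% aug$negative_ids))
  expect_false(shared %in% aug$negative_ids)  # already an A positive
  expect_true(all(aug$positive_ids == t1[1:5]))
  # no siblings: training sets unchanged
  tree2 <- build_tree(w$docs, w$table,
                      tree_config(min_docs_for_split = 30, max_nodes = 7,
                                  max_passes = 2))
  attach_classifier(tree2, tree2$root, "solo",
                    positive_ids = t1[1:5], negative_ids = t2[1:5])
  solo <- augment_training(tree2, "solo")
  expect_equal(sort(solo$negative_ids), sort(t2[1:5]))
})
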