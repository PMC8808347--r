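#' Depth level with the most clustering nodes
#'
#' Active-learning candidates are drawn from the widest tree level,
#' where documents are assumed to be best spread over the vector space.
#' Ties break toward the deeper level (more, smaller nodes).
#'
#' @param tree A `topic_tree`.
#' @param root Subtree root id; defaults to the whole tree.
#' @return Integer depth, relative to the tree root.
#' @export
dmax_level <- function(tree, root = tree$root) {
  ids <- subtree_ids(tree, root)
  ids <- ids[tree$type[ids] == "cluster"]
  if (!length(ids)) stop("subtree has no clustering node")
  depths <- tree$depth[ids]
  tab <- table(depths)
  lv <- as.integer(names(tab))
  best <- lv[tab == max(tab)]
  max(best)
}

subtree_ids <- function(tree, root) {
  out <- integer(0)
  todo <- root
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    out <- c(out, cur)
    for (ch in c(tree$left[cur], tree$right[cur])) {
      if (ch != 0L) todo <- c(todo, ch)
    }
  }
  out
}

# clustering nodes of a subtree at its dmax level, in id order
dmax_nodes <- function(tree, root) {
  ids <- subtree_ids(tree, root)
  ids <- ids[tree$type[ids] == "cluster"]
  lv <- dmax_level(tree, root)
  sort(ids[tree$depth[ids] == lv])
}

#' Uncertainty distance of a predicted probability
#'
#' Distance of the calibrated positive-class probability from 0.5;
#' smaller means more uncertain, so the most informative document under
#' uncertainty sampling minimizes this.
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Values in `[0, 0.5]`.
#' @export
uncertainty_distance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probability outside [0, 1]")
  abs(p - 0.5)
}

#' Initial round-robin batch from the widest tree level
#'
#' Cycles over the clustering nodes at the tree's widest depth level,
#' drawing one uniformly random unlabeled assigned document per node per
#' cycle (exhausted nodes are skipped) until `batch_size` documents are
#' collected or the pool runs out.
#'
#' @param tree A built `topic_tree` (clustering only at iteration 1).
#' @param batch_size Number of documents to select (default 50).
#' @param rng_seed Integer seed making the draw reproducible.
#' @param labeled Character vector of already labeled ids to exclude.
#' @return Character vector of selected document ids.
#' @export
initial_batch <- function(tree, batch_size = 50L, rng_seed = 1L,
                          labeled = character()) {
  nodes <- dmax_nodes(tree, tree$root)
  pools <- lapply(nodes, function(id) {
    setdiff(node_doc_ids(tree, id), labeled)
  })
  if (!sum(lengths(pools))) stop("no unlabeled assigned documents")
  with_seed(rng_seed, {
    sel <- character(0)
    while (length(sel) < batch_size && sum(lengths(pools)) > 0) {
      for (j in seq_along(pools)) {
        if (length(sel) >= batch_size) break
        if (!length(pools[[j]])) next
        pick <- pools[[j]][sample.int(length(pools[[j]]), 1L)]
        sel <- c(sel, pick)
        pools[[j]] <- setdiff(pools[[j]], pick)
      }
    }
    sel
  })
}

# round-robin uncertainty draw within one subtree: per node per cycle,
# take the unlabeled document whose probability is closest to 0.5
subtree_uncertain <- function(tree, root, prob_by_id, n_want, labeled) {
  if (root == 0L || n_want <= 0L) return(character(0))
  nodes <- tryCatch(dmax_nodes(tree, root), error = function(e) integer(0))
  if (!length(nodes)) return(character(0))
  pools <- lapply(nodes, function(id) {
    setdiff(node_doc_ids(tree, id), labeled)
  })
  sel <- character(0)
  while (length(sel) < n_want && sum(lengths(pools)) > 0) {
    for (j in seq_along(pools)) {
      if (length(sel) >= n_want) break
      ids <- pools[[j]]
      if (!length(ids)) next
      d <- uncertainty_distance(prob_by_id[ids])
      pick <- ids[order(d, ids)[1]]  # deterministic tie-break by id
      sel <- c(sel, pick)
      pools[[j]] <- setdiff(ids, pick)
    }
  }
  sel
}

#' Tree-structured uncertainty batch
#'
#' Splits the selection between the positive tree (the clustering subtree
#' under the classifier) and the negative tree (under its clustering
#' brother): within each, the widest level is located, its nodes are
#' cycled round-robin and each node contributes its most uncertain
#' unlabeled document (probability closest to 0.5) per cycle until
#' `floor(batch_size / 2)` are collected (the positive tree takes the
#' extra draw when `batch_size` is odd).  If one subtree exhausts, the
#' remainder is drawn from the other.
#'
#' @param tree A `topic_tree`, or `NULL` when the positive/negative roots
#'   come from two separate trees.
#' @param model A `margin_model` scoring the documents.
#' @param batch_size Number of documents to select.
#' @param labeled Ids to exclude.
#' @param pos_root,neg_root Root ids of the positive and negative
#'   subtrees; either may be 0 (absent).
#' @param pos_tree,neg_tree Alternative interface: two separate
#'   `topic_tree`s holding the accepted and rejected documents.
#' @return Character vector of selected document ids.
#' @export
uncertain_batch <- function(tree = NULL, model, batch_size = 50L,
                            labeled = character(),
                            pos_root = 0L, neg_root = 0L,
                            pos_tree = NULL, neg_tree = NULL) {
  if (is.null(pos_tree)) { pos_tree <- tree } else { pos_root <- pos_tree$root }
  if (is.null(neg_tree)) { neg_tree <- tree } else { neg_root <- neg_tree$root }
  if ((is.null(pos_tree) || pos_root == 0L) &&
      (is.null(neg_tree) || neg_root == 0L)) {
    stop("both subtrees are empty")
  }
  prob_for <- function(tr) {
    p <- predict_margin(model, tr$docs$vectors)
    names(p) <- tr$docs$ids
    p
  }
  half_pos <- ceiling(batch_size / 2)
  half_neg <- batch_size - half_pos
  pos_sel <- if (!is.null(pos_tree) && pos_root != 0L) {
    subtree_uncertain(pos_tree, pos_root, prob_for(pos_tree), half_pos, labeled)
  } else character(0)
  neg_sel <- if (!is.null(neg_tree) && neg_root != 0L) {
    subtree_uncertain(neg_tree, neg_root, prob_for(neg_tree), half_neg,
                      c(labeled, pos_sel))
  } else character(0)
  sel <- c(pos_sel, neg_sel)
  rem <- batch_size - length(sel)
  if (rem > 0) {  # one side exhausted: top up from the other
    extra_pos <- if (!is.null(pos_tree) && pos_root != 0L) {
      subtree_uncertain(pos_tree, pos_root, prob_for(pos_tree), rem,
                        c(labeled, sel))
    } else character(0)
    sel <- c(sel, extra_pos)
    rem <- batch_size - length(sel)
    if (rem > 0 && !is.null(neg_tree) && neg_root != 0L) {
      sel <- c(sel, subtree_uncertain(neg_tree, neg_root,
                                      prob_for(neg_tree), rem,
                                      c(labeled, sel)))
    }
  }
  sel
}

#' Random baseline batch
#'
#' @param pool Character vector of unlabeled document ids.
#' @param batch_size Number to draw (uniform, without replacement; the
#'   whole pool when smaller).
#' @param rng_seed Integer seed.
#' @return Character vector of selected ids.
#' @export
random_batch <- function(pool, batch_size = 50L, rng_seed = 1L) {
  if (!length(pool)) stop("empty pool")
  n <- min(batch_size, length(pool))
  with_seed(rng_seed, pool[sample.int(length(pool), n)])
}

#' Pool-based uncertainty baseline batch
#'
#' Classic uncertainty sampling without the tree: the `batch_size` pool
#' documents whose predicted probability is globally closest to 0.5.
#'
#' @param pool Character vector of unlabeled document ids.
#' @param probs Probabilities named by document id (covering the pool).
#' @param batch_size Number to select.
#' @return Character vector of selected ids.
#' @export
pool_uncertainty_batch <- function(pool, probs, batch_size = 50L) {
  if (!length(pool)) stop("empty pool")
  d <- uncertainty_distance(probs[pool])
  pool[order(d, pool)][seq_len(min(batch_size, length(pool)))]
}

#' Simulation configuration for active-learning benchmarks
#'
#' @param batch_size Labels revealed per iteration (default 50).
#' @param checkpoints Label counts at which the test set is scored
#'   (default 50, 100, 150, 200).
#' @param train_size,test_size Pool and test sizes for the random split
#'   (defaults 1000/1000).
#' @param seed Simulation seed (split, batches).
#' @param tree Tree configuration used for the clustering trees the
#'   tree-structured strategy builds; kept small (31 nodes, 2 passes,
#'   split threshold 25) because these trees are rebuilt after every
#'   batch.
#' @param cost SVM regularization strength.
#' @return An `al_config` list.
#' @export
al_config <- function(batch_size = 50L,
                      checkpoints = c(50L, 100L, 150L, 200L),
                      train_size = 1000L, test_size = 1000L, seed = 1L,
                      tree = tree_config(min_docs_for_split = 25L,
                                         max_nodes = 31L, max_passes = 2L),
                      cost = 1) {
  stopifnot(batch_size >= 1, all(diff(checkpoints) > 0))
  structure(list(batch_size = as.integer(batch_size),
                 checkpoints = as.integer(checkpoints),
                 train_size = as.integer(train_size),
                 test_size = as.integer(test_size),
                 seed = as.integer(seed), tree = tree, cost = cost),
            class = "al_config")
}

#' Checkpointed active-learning simulation
#'
#' Simulates the labeling workflow one class at a time, one-vs-rest: the
#' class's documents are the positive class, everything else negative.
#' The corpus is split into a labeling pool and a held-out test set; at
#' every iteration the strategy selects a batch, the gold verdicts are
#' revealed, the classifier is retrained, and (for the tree strategy)
#' the positive/negative clustering trees are rebuilt.  The test set is
#' scored at each checkpoint.
#'
#' Strategies: `"random"` (uniform), `"pool_uncertainty"` (global
#' uncertainty sampling), `"tree_dmax"` (round-robin uncertainty sampling
#' over the widest level of the positive and negative trees; its first
#' batch is drawn round-robin from the initial clustering tree, the
#' baselines start from a random batch).  Until a batch contains both a
#' positive and a negative verdict no model exists: selection falls back
#' to random/round-robin and the test score is the all-negative
#' prediction.
#'
#' @param docs A labeled `document_set`.
#' @param strategy `"random"`, `"pool_uncertainty"` or `"tree_dmax"`.
#' @param config An [al_config()].
#' @param table The [embedding_table()] (needed by the tree strategy).
#' @param classes Classes to simulate; defaults to all labels present.
#' @return An `al_report`: per-class metrics at every checkpoint, the
#'   weighted averages (weights = test-set support), and the number of
#'   positive training instances found per checkpoint.
#' @export
run_al_simulation <- function(docs, strategy = c("tree_dmax", "random",
                                                 "pool_uncertainty"),
                              config = al_config(), table = NULL,
                              classes = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "tree_dmax" && is.null(table)) {
    stop("the tree strategy needs the embedding table")
  }
  if (any(is.na(docs$labels))) stop("simulation needs a fully labeled corpus")
  n_need <- config$train_size + config$test_size
  if (docs$n < n_need) stop("corpus smaller than train_size + test_size")
  perm <- with_seed(config$seed, sample.int(docs$n))
  pool_i <- perm[seq_len(config$train_size)]
  test_i <- perm[config$train_size + seq_len(config$test_size)]
  pool <- subset_docs(docs, pool_i)
  test <- subset_docs(docs, test_i)
  if (is.null(classes)) classes <- sort(unique(docs$labels))
  max_labels <- max(config$checkpoints)

  pool_tree <- NULL
  if (strategy == "tree_dmax") {
    pool_tree <- build_tree(pool, table, config$tree)
  }

  per_class <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    gold <- pool$labels == cl
    labeled <- character(0)
    model <- NULL
    rows <- list()
    iter <- 0L
    while (length(labeled) < max_labels && length(labeled) < pool$n) {
      iter <- iter + 1L
      bs <- min(config$batch_size, max_labels - length(labeled))
      bseed <- (config$seed * 1009L + ci * 101L + iter * 7L) %%
        .Machine$integer.max
      unl <- setdiff(pool$ids, labeled)
      batch <- if (is.null(model)) {
        if (strategy == "tree_dmax") {
          initial_batch(pool_tree, bs, bseed, labeled)
        } else {
          random_batch(unl, bs, bseed)
        }
      } else if (strategy == "random") {
        random_batch(unl, bs, bseed)
      } else if (strategy == "pool_uncertainty") {
        p <- predict_margin(model, pool$vectors)
        names(p) <- pool$ids
        pool_uncertainty_batch(unl, p, bs)
      } else {
        p <- predict_margin(model, pool$vectors)
        acc <- p >= 0.5
        pos_tree <- if (any(acc)) {
          build_tree(subset_docs(pool, which(acc)), table, config$tree)
        }
        neg_tree <- if (any(!acc)) {
          build_tree(subset_docs(pool, which(!acc)), table, config$tree)
        }
        if (is.null(pos_tree) && is.null(neg_tree)) {
          random_batch(unl, bs, bseed)
        } else {
          uncertain_batch(model = model, batch_size = bs, labeled = labeled,
                          pos_tree = pos_tree, neg_tree = neg_tree)
        }
      }
      if (!length(batch)) break
      labeled <- c(labeled, batch)
      y <- gold[match(labeled, pool$ids)]
      if (any(y) && any(!y)) {
        model <- train_margin_classifier(
          pool$vectors[match(labeled[y], pool$ids), , drop = FALSE],
          pool$vectors[match(labeled[!y], pool$ids), , drop = FALSE],
          cost = config$cost)
      }
      if (length(labeled) %in% config$checkpoints) {
        pred <- if (is.null(model)) rep(FALSE, test$n)
                else predict_margin(model, test$vectors) >= 0.5
        truth <- test$labels == cl
        tp <- sum(pred & truth); fp <- sum(pred & !truth)
        fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
        prec <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec <- if (tp + fn > 0) tp / (tp + fn) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, checkpoint = length(labeled),
          support = sum(truth),
          accuracy = (tp + tn) / test$n, precision = prec, recall = rec,
          f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
          positives_found = sum(y), stringsAsFactors = FALSE)
      }
    }
    per_class[[ci]] <- do.call(rbind, rows)
  }
  detail <- do.call(rbind, per_class)
  weighted <- do.call(rbind, lapply(sort(unique(detail$checkpoint)),
                                    function(ck) {
    d <- detail[detail$checkpoint == ck, ]
    w <- d$support / sum(d$support)
    data.frame(checkpoint = ck,
               accuracy = sum(w * d$accuracy),
               precision = sum(w * d$precision),
               recall = sum(w * d$recall),
               f1 = sum(w * d$f1))
  }))
  structure(list(strategy = strategy, per_class = detail,
                 weighted = weighted, config = config),
            class = "al_report")
}

#' @export
print.al_report <- function(x, ...) {
  cat(sprintf("<al_report> strategy %s, %d classes\n", x$strategy,
              length(unique(x$per_class$class))))
  print(x$weighted, row.names = FALSE, digits = 4)
  invisible(x)
}
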