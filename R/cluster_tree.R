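#' Configuration for streaming tree construction
#'
#' @param min_docs_for_split Minimum documents a leaf must absorb before it
#'   splits into two children (default 50).
#' @param max_nodes Maximum number of clustering nodes in the tree; a
#'   binary tree with `L` leaves has `2L - 1` nodes, so 63 yields 32
#'   leaves.  Classifier nodes and discard bins do not count against it.
#' @param k_headwords Number of headwords kept per node (default 10).
#' @param max_passes Maximum number of streaming passes, including the
#'   initial growth pass (default 10).
#' @param convergence_tol Refinement stops once the summed headword
#'   objective improves by less than this (default 1e-9).
#' @param seed Integer recorded with the tree; used by helpers that
#'   shuffle document order.
#' @return A `tree_config` list.
#' @export
tree_config <- function(min_docs_for_split = 50L, max_nodes = 63L,
                        k_headwords = 10L, max_passes = 10L,
                        convergence_tol = 1e-9, seed = 1L) {
  stopifnot(min_docs_for_split >= 2, max_nodes >= 1, k_headwords >= 1,
            max_passes >= 1, convergence_tol > 0)
  structure(list(min_docs_for_split = as.integer(min_docs_for_split),
                 max_nodes = as.integer(max_nodes),
                 k_headwords = as.integer(k_headwords),
                 max_passes = as.integer(max_passes),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed)),
            class = "tree_config")
}

# ---- internal node bookkeeping -------------------------------------------
# A topic_tree is an environment holding parallel per-node vectors/lists:
#   type ("cluster"/"classifier"/"bin"), parent, depth, left, right
#   (left/right are child ids, 0 = none; for classifiers left = accept
#   child, right = reject brother/bin), doc_count, and per-node lists for
#   the token-count accumulator, embedding sum, assigned doc indices,
#   headword indices, cumulative headword objectives, and the cached
#   vocabulary routing-score vector.  The streaming property lives here:
#   no per-document vector or text is ever stored on a node.

add_node <- function(tree, type, parent, depth) {
  id <- length(tree$type) + 1L
  tree$type[id] <- type
  tree$parent[id] <- parent
  tree$depth[id] <- depth
  tree$left[id] <- 0L
  tree$right[id] <- 0L
  tree$doc_count[id] <- 0
  V <- if (is.null(tree$table)) 0L else vocab_size(tree$table)
  tree$counts[id] <- list(if (type == "cluster") numeric(V))
  tree$vec_sum[id] <- list(if (type == "cluster") numeric(tree$dim))
  tree$doc_idx[[id]] <- integer(0)
  tree$hw[[id]] <- integer(0)
  tree$hw_obj[[id]] <- numeric(0)
  tree$s[id] <- list(NULL)
  tree$cls_name[id] <- NA_character_
  tree$cls_pos[[id]] <- character(0)
  tree$cls_neg[[id]] <- character(0)
  tree$cls_model[id] <- list(NULL)
  tree$cls_seeded[id] <- FALSE
  if (type == "cluster") tree$n_cluster <- tree$n_cluster + 1L
  id
}

#' Initialize an empty topic tree
#'
#' Creates a tree with a single root clustering node over a vectorized
#' corpus.  Documents are fed in with [insert_document()] or, more
#' usually, via [build_tree()].
#'
#' @param docs A `document_set` from [vectorize_corpus()].
#' @param table The matching [embedding_table()].
#' @param config A [tree_config()].
#' @return A `topic_tree` (an environment; modified in place by the
#'   streaming operations).
#' @export
new_tree <- function(docs, table, config = tree_config()) {
  stopifnot(inherits(docs, "document_set"), inherits(table, "embedding_table"))
  tree <- new.env(parent = emptyenv())
  tree$table <- table
  tree$docs <- docs
  tree$cfg <- config
  tree$dim <- table$dim
  tree$type <- character(0); tree$parent <- integer(0)
  tree$depth <- integer(0); tree$left <- integer(0); tree$right <- integer(0)
  tree$doc_count <- numeric(0)
  tree$counts <- list(); tree$vec_sum <- list(); tree$doc_idx <- list()
  tree$hw <- list(); tree$hw_obj <- list(); tree$s <- list()
  tree$cls_name <- character(0)
  tree$cls_pos <- list(); tree$cls_neg <- list(); tree$cls_model <- list()
  tree$cls_seeded <- logical(0)
  tree$n_cluster <- 0L
  tree$history <- numeric(0)
  tree$root <- 0L
  tree$root <- add_node(tree, "cluster", 0L, 0L)
  class(tree) <- "topic_tree"
  tree
}

#' @export
print.topic_tree <- function(x, ...) {
  nc <- sum(x$type == "cluster")
  nk <- sum(x$type == "classifier")
  leaves <- sum(x$type == "cluster" & x$left == 0L)
  cat(sprintf("<topic_tree> %d clustering nodes (%d leaves), %d classifier(s)\n",
              nc, leaves, nk))
  if (length(x$history)) {
    cat(sprintf("  passes: %d, summed headword objective: %.6f\n",
                length(x$history), x$history[length(x$history)]))
  }
  invisible(x)
}

# routing score vector over the whole vocabulary: for each token, the
# cosine to its closest headword of the node
score_vector <- function(tree, hw_idx) {
  U <- tree$table$unit
  M <- U %*% t(U[hw_idx, , drop = FALSE])
  s <- M[, 1]
  if (ncol(M) > 1) for (j in 2:ncol(M)) s <- pmax(s, M[, j])
  as.numeric(s)
}

# greedy forward headword selection from a node accumulator.
# Ties at the argmax break by higher token count, then lexicographically.
select_headwords_core <- function(counts, vec_sum, k, table) {
  obs <- which(counts > 0)
  if (!length(obs)) stop("empty accumulator: no observed tokens")
  S <- vec_sum
  Sn <- sqrt(sum(S^2))
  if (Sn == 0) stop("zero accumulator vector sum")
  Vm <- table$vectors[obs, , drop = FALSE]
  toks <- rownames(table$vectors)[obs]
  vs <- as.numeric(Vm %*% S)
  sq <- rowSums(Vm^2)
  cur <- numeric(length(S))
  cur_obj <- -Inf
  sel <- integer(0)
  cum <- numeric(0)
  k <- min(k, length(obs))
  for (step in seq_len(k)) {
    cross <- as.numeric(Vm %*% cur)
    num <- vs + sum(cur * S)
    den <- sqrt(pmax(sq + 2 * cross + sum(cur^2), 0)) * Sn
    obj <- ifelse(den > 0, num / den, -Inf)
    if (length(sel)) obj[sel] <- -Inf
    m <- max(obj)
    if (m <= cur_obj) break
    cand <- which(obj == m)
    if (length(cand) > 1) {
      cand <- cand[order(-counts[obs[cand]], toks[cand])]
    }
    pick <- cand[1]
    sel <- c(sel, pick)
    cur <- cur + Vm[pick, ]
    cur_obj <- m
    cum <- c(cum, m)
  }
  list(idx = obs[sel], obj = cum)
}

#' Headword objective of a token set at a node
#'
#' Cosine similarity between the summed embeddings of the given tokens
#' and the node's accumulated embedding sum (the sum of the word vectors
#' of every token occurrence that passed the node).
#'
#' @param tree A `topic_tree`.
#' @param node_id Clustering node id.
#' @param tokens Character vector of candidate headwords; defaults to the
#'   node's current headwords.
#' @return A number in `[-1, 1]`.
#' @export
headword_objective <- function(tree, node_id, tokens = NULL) {
  check_cluster(tree, node_id)
  if (is.null(tokens)) tokens <- headwords(tree, node_id)$token
  if (!length(tokens)) stop("empty headword set")
  idx <- match(tokens, rownames(tree$table$vectors))
  if (anyNA(idx)) stop("headword(s) not in embedding table: ",
                       paste(tokens[is.na(idx)], collapse = ", "))
  S <- tree$vec_sum[[node_id]]
  if (is.null(S) || sum(S^2) == 0) stop("node has an empty accumulator")
  h <- colSums(tree$table$vectors[idx, , drop = FALSE])
  cosine_sim(h, S)
}

#' Greedy headword selection for a node
#'
#' Starts from the empty set and repeatedly adds the observed token that
#' maximizes [headword_objective()] of the augmented set, stopping at `k`
#' tokens or when no addition improves the objective.
#'
#' @param tree A `topic_tree`.
#' @param node_id Clustering node id.
#' @param k Number of headwords; defaults to the tree's `k_headwords`.
#' @return Data frame with columns `token` and `objective` (the cumulative
#'   objective after adding each headword, in greedy order).
#' @export
select_headwords <- function(tree, node_id, k = tree$cfg$k_headwords) {
  check_cluster(tree, node_id)
  res <- select_headwords_core(tree$counts[[node_id]],
                               tree$vec_sum[[node_id]], k, tree$table)
  data.frame(token = rownames(tree$table$vectors)[res$idx],
             objective = res$obj, stringsAsFactors = FALSE)
}

#' Greedy headwords from a raw accumulator
#'
#' The same greedy forward selection as [select_headwords()], applied to
#' an explicit token-count accumulator rather than a tree node.
#'
#' @param counts Numeric vector of token occurrence counts, either of
#'   length `vocab_size(table)` (in vocabulary order) or named by token.
#' @param vec_sum The accumulated embedding sum; defaults to the sum
#'   implied by `counts`.
#' @param table An [embedding_table()].
#' @param k Maximum number of headwords.
#' @return Data frame with columns `token` and `objective`.
#' @export
greedy_headwords <- function(counts, vec_sum = NULL, table, k = 10L) {
  vocab <- rownames(table$vectors)
  if (!is.null(names(counts))) {
    full <- numeric(length(vocab))
    idx <- match(names(counts), vocab)
    if (anyNA(idx)) stop("count token(s) not in embedding table: ",
                         paste(names(counts)[is.na(idx)], collapse = ", "))
    full[idx] <- counts
    counts <- full
  }
  stopifnot(length(counts) == length(vocab))
  if (is.null(vec_sum)) vec_sum <- as.numeric(crossprod(table$vectors, counts))
  res <- select_headwords_core(counts, vec_sum, k, table)
  data.frame(token = vocab[res$idx], objective = res$obj,
             stringsAsFactors = FALSE)
}

#' Current headwords of a node
#' @inheritParams select_headwords
#' @return Data frame with columns `token` and `objective`.
#' @export
headwords <- function(tree, node_id) {
  toks <- if (!is.null(tree$table)) {
    rownames(tree$table$vectors)[tree$hw[[node_id]]]
  } else {
    tree$hw_tokens[[node_id]]
  }
  data.frame(token = as.character(toks),
             objective = as.numeric(tree$hw_obj[[node_id]]),
             stringsAsFactors = FALSE)
}

check_cluster <- function(tree, node_id) {
  if (node_id < 1 || node_id > length(tree$type) ||
      tree$type[node_id] != "cluster") {
    stop("node ", node_id, " is not a clustering node")
  }
  invisible(TRUE)
}

#' Affinity of a token sequence to a node's headwords
#'
#' The mean, over the in-vocabulary token occurrences, of the cosine
#' similarity of each token to its closest headword of the node.  This is
#' the per-child score used for routing and, against a node's own
#' headwords, the representativeness of a document.
#'
#' @param tokens Character vector of tokens (occurrences, not types).
#' @param tree A `topic_tree`.
#' @param node_id A clustering node with at least one headword.
#' @return A number in `[-1, 1]`.
#' @export
child_affinity <- function(tokens, tree, node_id) {
  check_cluster(tree, node_id)
  if (!length(tree$hw[[node_id]])) stop("node ", node_id, " has no headwords")
  idx <- match(tokens, rownames(tree$table$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no in-vocabulary token in document")
  s <- tree$s[[node_id]]
  if (is.null(s)) {
    s <- score_vector(tree, tree$hw[[node_id]])
    tree$s[[node_id]] <- s
  }
  mean(s[idx])
}

#' Route one document one level down
#'
#' Compares the document against the headwords of both clustering
#' children and returns the child with the strictly greater affinity;
#' exact ties go to the left child.
#'
#' @param tree A `topic_tree`.
#' @param node_id A clustering node with two clustering children.
#' @param doc Either a document id present in the tree's document set or
#'   a character vector of tokens.
#' @return The chosen child's node id.
#' @export
route_document <- function(tree, node_id, doc) {
  check_cluster(tree, node_id)
  if (tree$left[node_id] == 0L) stop("cannot route at a leaf node")
  tokens <- if (length(doc) == 1L && doc %in% tree$docs$ids) {
    doc_tokens(tree$docs, tree$table, doc)
  } else {
    as.character(doc)
  }
  al <- child_affinity(tokens, tree, tree$left[node_id])
  ar <- child_affinity(tokens, tree, tree$right[node_id])
  if (al >= ar) tree$left[node_id] else tree$right[node_id]
}

# split a leaf: seed the two children with the most mutually dissimilar
# pair of observed tokens (provisional headwords, replaced at the next
# pass-end re-selection).  Candidate tokens are capped at the 256 most
# frequent so the pairwise cosine matrix stays small.
split_leaf <- function(tree, leaf) {
  counts <- tree$counts[[leaf]]
  obs <- which(counts > 0)
  toks <- rownames(tree$table$vectors)[obs]
  if (length(obs) > 256L) {
    o <- order(-counts[obs], toks)[1:256]
    obs <- obs[o]; toks <- toks[o]
  }
  U <- tree$table$unit[obs, , drop = FALSE]
  M <- U %*% t(U)
  diag(M) <- Inf
  M <- (M + t(M)) / 2  # guard against tiny floating asymmetry
  mval <- min(M)
  hits <- which(M == mval, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  pairs <- cbind(pmin(toks[hits[, 1]], toks[hits[, 2]]),
                 pmax(toks[hits[, 1]], toks[hits[, 2]]))
  o <- order(pairs[, 1], pairs[, 2])[1]
  i <- hits[o, 1]; j <- hits[o, 2]
  # left child takes the more frequent seed token; ties lexicographic
  if (counts[obs[j]] > counts[obs[i]] ||
      (counts[obs[j]] == counts[obs[i]] && toks[j] < toks[i])) {
    tmp <- i; i <- j; j <- tmp
  }
  d <- tree$depth[leaf] + 1L
  lid <- add_node(tree, "cluster", leaf, d)
  rid <- add_node(tree, "cluster", leaf, d)
  tree$left[leaf] <- lid
  tree$right[leaf] <- rid
  for (ch in c(lid, rid)) {
    seed <- if (ch == lid) obs[i] else obs[j]
    tree$hw[[ch]] <- seed
    tree$hw_obj[[ch]] <- NA_real_
    tree$s[[ch]] <- as.numeric(tree$table$unit %*% tree$table$unit[seed, ])
  }
  invisible(tree)
}

# stream one document (by index into tree$docs) from the root to a leaf,
# updating accumulators and splitting leaves that reached the threshold
descend_doc <- function(tree, di) {
  docs <- tree$docs
  u <- docs$u_idx[[di]]
  cnt <- docs$u_cnt[[di]]
  tsum <- docs$tok_sums[di, ]
  vec <- docs$vectors[di, ]
  min_split <- tree$cfg$min_docs_for_split
  max_nodes <- tree$cfg$max_nodes
  cur <- tree$root
  repeat {
    ty <- tree$type[cur]
    if (ty == "classifier") {
      m <- tree$cls_model[[cur]]
      acc <- !is.null(m) && predict_margin(m, vec) >= 0.5
      cur <- if (acc) tree$left[cur] else tree$right[cur]
      next
    }
    if (ty == "bin") {
      tree$doc_count[cur] <- tree$doc_count[cur] + 1
      tree$doc_idx[[cur]] <- c(tree$doc_idx[[cur]], di)
      break
    }
    tree$counts[[cur]][u] <- tree$counts[[cur]][u] + cnt
    tree$vec_sum[[cur]] <- tree$vec_sum[[cur]] + tsum
    tree$doc_count[cur] <- tree$doc_count[cur] + 1
    tree$doc_idx[[cur]] <- c(tree$doc_idx[[cur]], di)
    if (tree$left[cur] == 0L) {
      if (tree$doc_count[cur] >= min_split &&
          tree$n_cluster + 2L <= max_nodes &&
          sum(tree$counts[[cur]] > 0) >= 2L) {
        split_leaf(tree, cur)
      } else {
        break
      }
    }
    lid <- tree$left[cur]
    if (lid == 0L) break
    rid <- tree$right[cur]
    al <- sum(cnt * tree$s[[lid]][u])
    ar <- sum(cnt * tree$s[[rid]][u])
    cur <- if (al >= ar) lid else rid
  }
  invisible(cur)
}

#' Stream one document into the tree
#'
#' The document descends from the root, updating each visited node's
#' accumulator, document count and assigned ids.  When it lands on a leaf
#' that has absorbed at least `min_docs_for_split` documents (and the
#' node budget allows), the leaf splits into two children seeded with the
#' most mutually dissimilar pair of tokens observed at the leaf, and the
#' document is routed into one of them.
#'
#' @param tree A `topic_tree`.
#' @param doc_id A document id present in the tree's document set.
#' @return The id of the node where the document came to rest (invisibly).
#' @export
insert_document <- function(tree, doc_id) {
  di <- match(doc_id, tree$docs$ids)
  if (is.na(di)) stop("unknown document id: ", doc_id)
  if (!length(tree$docs$token_idx[[di]])) stop("empty document: ", doc_id)
  invisible(descend_doc(tree, di))
}

reset_pass_state <- function(tree) {
  for (id in seq_along(tree$type)) {
    if (tree$type[id] == "cluster") {
      tree$counts[[id]][] <- 0
      tree$vec_sum[[id]][] <- 0
    }
    tree$doc_count[id] <- 0
    tree$doc_idx[[id]] <- integer(0)
  }
  invisible(tree)
}

# one full streaming pass over the document set; headwords re-selected at
# pass end from the fresh accumulators (nodes untouched this pass keep
# their previous headwords)
stream_pass <- function(tree) {
  reset_pass_state(tree)
  for (id in seq_along(tree$type)) {
    if (tree$type[id] == "cluster" && length(tree$hw[[id]]) &&
        is.null(tree$s[[id]])) {
      tree$s[[id]] <- score_vector(tree, tree$hw[[id]])
    }
  }
  for (di in seq_len(tree$docs$n)) descend_doc(tree, di)
  refresh_headwords(tree)
  invisible(tree)
}

refresh_headwords <- function(tree) {
  k <- tree$cfg$k_headwords
  for (id in seq_along(tree$type)) {
    if (tree$type[id] != "cluster" || tree$doc_count[id] == 0) next
    res <- select_headwords_core(tree$counts[[id]], tree$vec_sum[[id]],
                                 k, tree$table)
    tree$hw[[id]] <- res$idx
    tree$hw_obj[[id]] <- res$obj
    tree$s[[id]] <- score_vector(tree, res$idx)
  }
  invisible(tree)
}

# summed headword objective over populated clustering nodes
objective_sum <- function(tree) {
  tot <- 0
  for (id in seq_along(tree$type)) {
    if (tree$type[id] != "cluster") next
    hw <- tree$hw[[id]]
    S <- tree$vec_sum[[id]]
    if (!length(hw) || sum(S^2) == 0) next
    h <- colSums(tree$table$vectors[hw, , drop = FALSE])
    tot <- tot + cosine_sim(h, S)
  }
  tot
}

snapshot_tree <- function(tree) {
  fields <- c("type", "parent", "depth", "left", "right", "doc_count",
              "counts", "vec_sum", "doc_idx", "hw", "hw_obj", "s",
              "cls_name", "cls_pos", "cls_neg", "cls_model", "cls_seeded",
              "n_cluster", "root", "history")
  mget(fields, envir = tree)
}

restore_tree <- function(tree, snap) {
  for (f in names(snap)) assign(f, snap[[f]], envir = tree)
  invisible(tree)
}

#' Build a topic tree by streaming passes
#'
#' Streams the documents one by one to grow the tree, then repeats full
#' passes ([refine()]) so headwords keep improving until the summed
#' headword objective reaches a local maximum or `max_passes` passes have
#' run.  Accumulators and assignments are reset at the start of each
#' pass; splits may occur on any pass subject to `max_nodes`.
#'
#' @param docs A `document_set` from [vectorize_corpus()].
#' @param table The matching [embedding_table()].
#' @param config A [tree_config()].
#' @param order_seed Optional integer; when given, the document order is
#'   shuffled with this seed before building (the streaming tree depends
#'   on document order).
#' @return A `topic_tree` with `tree$history` holding the summed headword
#'   objective after each accepted pass (a non-decreasing sequence).
#' @export
build_tree <- function(docs, table, config = tree_config(),
                       order_seed = NULL) {
  if (!is.null(order_seed)) {
    perm <- with_seed(order_seed, sample.int(docs$n))
    docs <- subset_docs(docs, perm)
  }
  tree <- new_tree(docs, table, config)
  refine(tree, max_passes = config$max_passes)
  tree
}

#' Refinement passes over an existing tree
#'
#' Re-streams the whole document set, re-selecting every node's headwords
#' from the pass's accumulator, for up to `max_passes` total passes.  The
#' loop stops when a pass fails to improve the summed headword objective
#' by at least `convergence_tol`; a pass that would lower the objective
#' is rolled back, so the recorded objective sequence is non-decreasing
#' and the tree is left at a local maximum of the summed objective.
#'
#' @param tree A `topic_tree`.
#' @param max_passes Maximum number of passes to run in this call.
#' @return The tree, invisibly (modified in place).
#' @export
refine <- function(tree, max_passes = tree$cfg$max_passes) {
  tol <- tree$cfg$convergence_tol
  prev <- if (length(tree$history)) tree$history[length(tree$history)] else -Inf
  for (pass in seq_len(max_passes)) {
    snap <- if (is.finite(prev)) snapshot_tree(tree) else NULL
    stream_pass(tree)
    obj <- objective_sum(tree)
    if (is.finite(prev) && obj - prev < tol) {
      if (obj < prev) {
        restore_tree(tree, snap)
      } else {
        tree$history <- c(tree$history, obj)
      }
      break
    }
    tree$history <- c(tree$history, obj)
    prev <- obj
  }
  invisible(tree)
}

#' Representativeness ranking of a node's documents
#'
#' Scores every document assigned to the node by its affinity to the
#' node's own headwords and returns them ordered from the most to the
#' least representative (or reversed, which surfaces the documents the
#' headwords describe worst).
#'
#' @param tree A `topic_tree`.
#' @param node_id A clustering node with headwords.
#' @param decreasing Order flag; `TRUE` (default) ranks the most
#'   representative document first.
#' @return Data frame with columns `id` and `score`.
#' @export
representativeness <- function(tree, node_id, decreasing = TRUE) {
  check_cluster(tree, node_id)
  if (!length(tree$hw[[node_id]])) stop("node ", node_id, " has no headwords")
  di <- tree$doc_idx[[node_id]]
  if (!length(di)) stop("no documents assigned to node ", node_id)
  s <- tree$s[[node_id]]
  sc <- vapply(di, function(i) {
    mean(s[tree$docs$token_idx[[i]]])
  }, numeric(1))
  o <- order(sc, tree$docs$ids[di], decreasing = decreasing)
  data.frame(id = tree$docs$ids[di][o], score = sc[o],
             stringsAsFactors = FALSE)
}

#' Document ids assigned at a node
#'
#' Membership is transitive: a node's assigned set contains every
#' document that passed through it on the most recent pass, so an
#' internal node contains the union of its children.
#'
#' @param tree A `topic_tree` (built, or loaded with [load_tree()]).
#' @param node_id Node id.
#' @return Character vector of document ids.
#' @export
node_doc_ids <- function(tree, node_id) {
  if (!is.null(tree$docs)) {
    tree$docs$ids[tree$doc_idx[[node_id]]]
  } else {
    tree$doc_ids_store[[node_id]]
  }
}

#' Number of nodes in the tree
#' @param tree A `topic_tree`.
#' @param type Optional filter: "cluster", "classifier" or "bin".
#' @export
n_nodes <- function(tree, type = NULL) {
  if (is.null(type)) length(tree$type) else sum(tree$type == type)
}
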