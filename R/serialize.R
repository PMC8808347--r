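#' Serialize a topic tree to JSON
#'
#' Writes a single JSON document: the configuration, root id, objective
#' history, and one record per node with its id, type, depth, parent,
#' child ids, headwords (token plus cumulative objective contribution),
#' document count, assigned document ids and -- for classifier nodes --
#' the topic name, training ids and calibrated linear model.  No document
#' text or per-document vector is stored, so file size is governed by the
#' number of nodes, not the corpus.  Serialization is deterministic:
#' identical builds produce byte-identical files.
#'
#' @param tree A `topic_tree`.
#' @param path Output path; with `NULL`, the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
save_tree <- function(tree, path = NULL) {
  vocab <- if (!is.null(tree$table)) rownames(tree$table$vectors) else NULL
  nodes <- lapply(seq_along(tree$type), function(id) {
    nd <- list(node_id = id, type = tree$type[id],
               depth = tree$depth[id], parent = tree$parent[id])
    ch <- c(tree$left[id], tree$right[id])
    nd$children <- as.integer(ch[ch != 0L])
    if (tree$type[id] == "cluster") {
      toks <- if (!is.null(vocab)) vocab[tree$hw[[id]]]
              else tree$hw_tokens[[id]]
      nd$headwords <- lapply(seq_along(toks), function(i) {
        list(token = toks[i], objective = tree$hw_obj[[id]][i])
      })
    }
    if (tree$type[id] == "classifier") {
      nd$name <- tree$cls_name[id]
      nd$positive_ids <- as.character(tree$cls_pos[[id]])
      nd$negative_ids <- as.character(tree$cls_neg[[id]])
      nd$seeded <- tree$cls_seeded[id]
      m <- tree$cls_model[[id]]
      if (!is.null(m)) {
        nd$model <- list(w = as.numeric(m$w), b = m$b,
                         platt = as.numeric(m$platt), base = m$base,
                         cost = m$cost, dim = m$dim)
      }
    }
    nd$doc_count <- as.integer(tree$doc_count[id])
    nd$doc_ids <- as.character(node_doc_ids(tree, id))
    nd
  })
  obj <- list(format = "topictree/1",
              config = unclass(tree$cfg),
              root = tree$root,
              objective_history = tree$history,
              nodes = nodes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Load a serialized topic tree
#'
#' Reconstructs the tree structure, headwords, assignments and classifier
#' models from JSON.  The loaded tree supports inspection, evaluation and
#' active-learning selection directly; to resume streaming operations
#' (rebuilds, feedback), re-attach the corpus and embeddings with
#' [attach_corpus()].
#'
#' @param path Path to a file written by [save_tree()].
#' @return A `topic_tree`.
#' @export
load_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "topictree/1") {
    stop("not a topictree serialization: ", path)
  }
  tree <- new.env(parent = emptyenv())
  tree$table <- NULL; tree$docs <- NULL
  cfg <- obj$config
  tree$cfg <- do.call(tree_config, cfg[intersect(names(cfg),
    names(formals(tree_config)))])
  tree$dim <- NA_integer_
  n <- length(obj$nodes)
  tree$type <- character(n); tree$parent <- integer(n)
  tree$depth <- integer(n); tree$left <- integer(n); tree$right <- integer(n)
  tree$doc_count <- numeric(n)
  tree$counts <- vector("list", n); tree$vec_sum <- vector("list", n)
  tree$doc_idx <- vector("list", n)
  tree$hw <- vector("list", n); tree$hw_obj <- vector("list", n)
  tree$hw_tokens <- vector("list", n)
  tree$s <- vector("list", n)
  tree$cls_name <- rep(NA_character_, n)
  tree$cls_pos <- vector("list", n); tree$cls_neg <- vector("list", n)
  tree$cls_model <- vector("list", n)
  tree$cls_seeded <- logical(n)
  tree$doc_ids_store <- vector("list", n)
  for (nd in obj$nodes) {
    id <- nd$node_id
    tree$type[id] <- nd$type
    tree$parent[id] <- nd$parent
    tree$depth[id] <- nd$depth
    ch <- unlist(nd$children)
    tree$left[id] <- if (length(ch) >= 1) ch[1] else 0L
    tree$right[id] <- if (length(ch) >= 2) ch[2] else 0L
    tree$doc_count[id] <- nd$doc_count
    tree$doc_ids_store[[id]] <- as.character(unlist(nd$doc_ids))
    tree$hw_tokens[[id]] <- vapply(nd$headwords, function(h)
      as.character(h$token), character(1))
    tree$hw_obj[[id]] <- vapply(nd$headwords, function(h)
      if (is.null(h$objective)) NA_real_ else as.numeric(h$objective),
      numeric(1))
    if (nd$type == "classifier") {
      tree$cls_name[id] <- nd$name
      tree$cls_pos[[id]] <- as.character(unlist(nd$positive_ids))
      tree$cls_neg[[id]] <- as.character(unlist(nd$negative_ids))
      tree$cls_seeded[id] <- isTRUE(nd$seeded)
      if (!is.null(nd$model)) {
        m <- nd$model
        tree$cls_model[[id]] <- structure(
          list(w = as.numeric(unlist(m$w)), b = m$b,
               platt = as.numeric(unlist(m$platt)), base = m$base,
               cost = m$cost, dim = m$dim),
          class = "margin_model")
      }
    }
  }
  tree$n_cluster <- sum(tree$type == "cluster")
  tree$root <- obj$root
  tree$history <- as.numeric(unlist(obj$objective_history))
  class(tree) <- "topic_tree"
  tree
}

#' Re-attach corpus and embeddings to a loaded tree
#'
#' Maps the stored headword tokens back to embedding indices and restores
#' the per-node accumulators exactly from the stored assignments (no
#' re-routing, so the tree state matches the serialized one), after which
#' the tree is fully operational again.
#'
#' @param tree A tree from [load_tree()].
#' @param docs A `document_set` for the same corpus.
#' @param table The matching [embedding_table()].
#' @return The tree, invisibly (modified in place).
#' @export
attach_corpus <- function(tree, docs, table) {
  tree$table <- table
  tree$docs <- docs
  tree$dim <- table$dim
  vocab <- rownames(table$vectors)
  n <- length(tree$type)
  for (id in seq_len(n)) {
    di <- match(tree$doc_ids_store[[id]], docs$ids)
    if (anyNA(di)) stop("document id(s) in tree missing from corpus ",
                        "at node ", id)
    tree$doc_idx[[id]] <- di
    tree$doc_count[id] <- length(di)
    if (tree$type[id] != "cluster") next
    idx <- match(tree$hw_tokens[[id]], vocab)
    if (anyNA(idx)) stop("headword token(s) missing from embedding table ",
                         "at node ", id)
    tree$hw[[id]] <- idx
    cnt <- numeric(length(vocab))
    for (i in di) cnt[docs$u_idx[[i]]] <- cnt[docs$u_idx[[i]]] + docs$u_cnt[[i]]
    tree$counts[[id]] <- cnt
    tree$vec_sum[[id]] <- if (length(di)) {
      colSums(docs$tok_sums[di, , drop = FALSE])
    } else {
      numeric(table$dim)
    }
  }
  tree$doc_ids_store <- NULL
  invisible(tree)
}
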