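#' Precision, recall and F1 of one node against one gold class
#'
#' @param class_docs Character vector of document ids in the gold class
#'   (non-empty).
#' @param node_docs Character vector of document ids assigned at a node.
#' @return Named numeric vector `c(precision, recall, f1)`; F1 is the
#'   harmonic mean and 0 when both components are 0.
#' @export
node_f1 <- function(class_docs, node_docs) {
  if (!length(class_docs)) stop("empty gold class")
  inter <- length(intersect(class_docs, node_docs))
  p <- if (length(node_docs)) inter / length(node_docs) else 0
  r <- inter / length(class_docs)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# shared core: node-wise doc-id sets + per-doc gold labels
hier_f1_core <- function(node_docs_list, doc_ids, doc_labels) {
  classes <- sort(unique(doc_labels))
  support <- vapply(classes, function(cl) sum(doc_labels == cl), numeric(1))
  nd_int <- lapply(node_docs_list, function(ids) match(ids, doc_ids))
  nd_len <- lengths(nd_int)
  best <- vapply(classes, function(cl) {
    cls <- which(doc_labels == cl)
    top <- 0
    for (j in seq_along(nd_int)) {
      inter <- sum(nd_int[[j]] %in% cls)
      if (inter == 0) next
      p <- inter / nd_len[j]
      r <- inter / length(cls)
      f <- 2 * p * r / (p + r)
      if (f > top) top <- f
    }
    top
  }, numeric(1))
  list(score = sum(best * support) / sum(support),
       per_class = data.frame(class = classes, support = support,
                              best_f1 = best, stringsAsFactors = FALSE,
                              row.names = NULL))
}

#' Hierarchical clustering F1
#'
#' Overall quality of a cluster hierarchy against gold classes: for each
#' gold class, the best F1 attained by any tree node (internal nodes and
#' leaves alike; membership is transitive, a document counts as a member
#' of every node it passed through), aggregated as the class-support
#' weighted mean.
#'
#' @param x A `topic_tree`, or a named list mapping node ids to character
#'   vectors of assigned document ids (as produced by
#'   [make_labeled_tree()]).
#' @param labels Gold labels: a character vector named by document id, or
#'   for a `topic_tree` built from a labeled corpus, `NULL` to use the
#'   corpus labels.
#' @param per_class Return the per-class table as well.
#' @return The weighted score in `[0, 1]`, or (with `per_class = TRUE`) a
#'   list with `score` and `per_class`.
#' @export
hierarchical_f1 <- function(x, labels = NULL, per_class = FALSE) {
  if (inherits(x, "topic_tree")) {
    node_docs <- lapply(seq_along(x$type), function(id) node_doc_ids(x, id))
    if (is.null(labels)) {
      if (is.null(x$docs)) stop("loaded tree needs explicit labels")
      labels <- structure(x$docs$labels, names = x$docs$ids)
      labels <- labels[!is.na(labels)]
    }
  } else {
    node_docs <- x
  }
  if (is.null(names(labels))) stop("labels must be named by document id")
  assigned <- unique(unlist(node_docs))
  miss <- setdiff(names(labels), assigned)
  if (length(miss)) stop("unassigned labeled document(s): ",
                         paste(head(miss, 5), collapse = ", "))
  node_docs <- lapply(node_docs, function(ids) ids[ids %in% names(labels)])
  res <- hier_f1_core(node_docs, names(labels), as.character(labels))
  if (per_class) res else res$score
}

#' One-vs-rest classification metrics with support weighting
#'
#' Computes per-class accuracy, precision, recall and F1 in the
#' one-vs-rest sense (the class is the positive side, everything else
#' negative) plus the class-support weighted averages.  Zero-division
#' cases (no predicted or no true positives) yield 0 and are flagged.
#'
#' @param y_true Character/factor vector of gold labels.
#' @param y_pred Either a label vector of the same length, or a logical
#'   matrix with one column per class (independent binary predictions,
#'   as produced by one-vs-rest classifiers).
#' @param classes Classes to report; defaults to those present in
#'   `y_true` (and the prediction columns).
#' @return A `metrics_table` data frame (one row per class) with a
#'   `weighted` attribute holding the support-weighted aggregates.
#' @export
classification_report <- function(y_true, y_pred,
                                  classes = NULL) {
  y_true <- as.character(y_true)
  pred_mat <- if (is.matrix(y_pred)) {
    if (nrow(y_pred) != length(y_true)) stop("length mismatch")
    y_pred
  } else {
    if (length(y_pred) != length(y_true)) stop("length mismatch")
    NULL
  }
  if (is.null(classes)) {
    classes <- if (is.null(pred_mat)) sort(unique(y_true))
               else colnames(pred_mat)
  }
  n <- length(y_true)
  rows <- lapply(classes, function(cl) {
    truth <- y_true == cl
    pred <- if (is.null(pred_mat)) as.character(y_pred) == cl
            else pred_mat[, cl]
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, support = sum(truth),
               accuracy = (tp + tn) / n, precision = prec, recall = rec,
               f1 = f1, zero_division = (tp + fp == 0) || (tp + fn == 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  w <- out$support / sum(out$support)
  attr(out, "weighted") <- c(accuracy = sum(w * out$accuracy),
                             precision = sum(w * out$precision),
                             recall = sum(w * out$recall),
                             f1 = sum(w * out$f1))
  class(out) <- c("metrics_table", class(out))
  out
}

#' Support-weighted aggregate metrics
#' @param report A `metrics_table` from [classification_report()].
#' @return Named numeric vector (accuracy, precision, recall, f1).
#' @export
weighted_metrics <- function(report) attr(report, "weighted")

#' @export
print.metrics_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  w <- attr(x, "weighted")
  cat(sprintf("weighted: acc %.4f  prec %.4f  rec %.4f  f1 %.4f\n",
              w["accuracy"], w["precision"], w["recall"], w["f1"]))
  invisible(x)
}

#' Clustering stability over random document orders
#'
#' The streaming tree depends on document order, so quality is reported
#' as the mean hierarchical F1 over repeated builds with shuffled orders,
#' with a normal-approximation 95% confidence interval.
#'
#' @param docs A labeled `document_set`.
#' @param table The matching [embedding_table()].
#' @param config A [tree_config()].
#' @param n_runs Number of repeated builds (>= 2; default 10).
#' @param seed Base seed; run `i` shuffles with `seed + i`.
#' @return List with `scores`, `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
repeated_build_summary <- function(docs, table, config = tree_config(),
                                   n_runs = 10, seed = 1L) {
  if (n_runs < 2) stop("n_runs must be at least 2")
  scores <- vapply(seq_len(n_runs), function(i) {
    tree <- build_tree(docs, table, config, order_seed = seed + i)
    hierarchical_f1(tree)
  }, numeric(1))
  m <- mean(scores)
  s <- stats::sd(scores)
  half <- stats::qnorm(0.975) * s / sqrt(n_runs)
  list(scores = scores, mean = m, sd = s,
       ci_lower = m - half, ci_upper = m + half)
}
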