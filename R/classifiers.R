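#' Train a binary maximum-margin topic classifier
#'
#' Fits a linear-kernel support vector machine on mean-embedding document
#' vectors and calibrates its decision values to probabilities with a
#' logistic (Platt) fit.  The linear weight vector is extracted from the
#' support vectors so the model is a plain `(w, b, platt)` triple:
#' serializable, fast to apply, and deterministic (the calibration is fit
#' on the training decision values, not on random cross-validation
#' folds).  On perfectly separable data the logistic fit diverges to a
#' steep sigmoid, which is harmless: ranks and the 0.5 threshold are
#' preserved.
#'
#' @param positives,negatives Numeric matrices of document vectors (one
#'   row per example); both classes need at least one example.
#' @param cost SVM regularization strength `C` (default 1).
#' @param seed Accepted for interface symmetry; the fit itself is
#'   deterministic.
#' @return A `margin_model`.
#' @export
train_margin_classifier <- function(positives, negatives, cost = 1,
                                    seed = 1L) {
  if (is.null(dim(positives))) positives <- matrix(positives, nrow = 1)
  if (is.null(dim(negatives))) negatives <- matrix(negatives, nrow = 1)
  if (!nrow(positives) || !nrow(negatives)) {
    stop("training error: both classes need at least one example")
  }
  stopifnot(ncol(positives) == ncol(negatives))
  X <- rbind(positives, negatives)
  y <- factor(rep(c("pos", "neg"), c(nrow(positives), nrow(negatives))),
              levels = c("neg", "pos"))
  fit <- tryCatch(
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE),
    error = function(e) stop("degenerate training set: ",
                             conditionMessage(e), call. = FALSE))
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dv <- as.numeric(X %*% w + b)
  yy <- as.integer(y == "pos")
  platt <- c(NA_real_, NA_real_)
  if (stats::sd(dv) > 1e-12) {
    g <- suppressWarnings(stats::glm(yy ~ dv, family = stats::binomial()))
    if (!anyNA(coef(g))) platt <- unname(coef(g))
  }
  structure(list(w = w, b = b, platt = platt, base = mean(yy),
                 cost = cost, dim = ncol(X)),
            class = "margin_model")
}

#' Calibrated positive-class probability
#'
#' @param model A `margin_model` from [train_margin_classifier()].
#' @param x A document vector, or a matrix with one document per row.
#' @return Probabilities in `[0, 1]`, one per document.
#' @export
predict_margin <- function(model, x) {
  if (!inherits(model, "margin_model")) stop("untrained or invalid model")
  if (is.null(dim(x))) x <- matrix(x, ncol = length(x))
  if (ncol(x) != model$dim) {
    stop("dimension mismatch: model expects ", model$dim, ", got ", ncol(x))
  }
  if (anyNA(model$platt)) return(rep(model$base, nrow(x)))
  dv <- as.numeric(x %*% model$w + model$b)
  stats::plogis(model$platt[1] + model$platt[2] * dv)
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("<margin_model> linear SVM, dim %d, cost %g\n", x$dim, x$cost))
  invisible(x)
}

#' Accept/reject decision of a classifier node
#'
#' A trained classifier node acts as a filter: a document with calibrated
#' probability at or above 0.5 is accepted and continues into the
#' classifier's clustering child; otherwise it is redirected to the
#' clustering brother (ties go to the positive side).
#'
#' @param tree A `topic_tree`.
#' @param node_id A classifier node id.
#' @param doc A document id in the tree's document set, or a raw vector.
#' @return `"accepted"` or `"rejected"`.
#' @export
filter_route <- function(tree, node_id, doc) {
  if (tree$type[node_id] != "classifier") {
    stop("node ", node_id, " is not a classifier node")
  }
  m <- tree$cls_model[[node_id]]
  if (is.null(m)) stop("classifier '", tree$cls_name[node_id],
                       "' is untrained")
  vec <- if (is.character(doc)) {
    di <- match(doc, tree$docs$ids)
    if (is.na(di)) stop("unknown document id: ", doc)
    tree$docs$vectors[di, ]
  } else {
    doc
  }
  if (predict_margin(m, vec) >= 0.5) "accepted" else "rejected"
}

recompute_depths <- function(tree) {
  todo <- tree$root
  tree$depth[tree$root] <- 0L
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    for (ch in c(tree$left[cur], tree$right[cur])) {
      if (ch != 0L) {
        tree$depth[ch] <- tree$depth[cur] + 1L
        todo <- c(todo, ch)
      }
    }
  }
  invisible(tree)
}

#' Create the In-Scope root classifier
#'
#' Installs a classifier above the current tree root, trained with each
#' seed word as a one-token positive pseudo-document and each stopword as
#' a one-token negative pseudo-document.  Accepted documents descend into
#' the existing clustering tree; rejected documents land in an
#' inspectable out-of-scope bin.  Seed words also present in the stopword
#' list are removed from the negatives.  Out-of-vocabulary seed words are
#' skipped with a warning; if none survives, it is an error.
#'
#' @param tree A `topic_tree`.
#' @param seed_words Character vector of topic-defining words, e.g.
#'   `c("diabetes", "insulin", "hypoglycemia", "pain", "treatment", "risk")`.
#' @param stopwords Negative pseudo-examples (default [stopwords_en()]).
#' @param cost SVM regularization strength.
#' @param rebuild Re-stream the documents through the new root
#'   (default TRUE).
#' @return The tree, invisibly (modified in place).
#' @export
make_in_scope <- function(tree, seed_words,
                          stopwords = stopwords_en(), cost = 1,
                          rebuild = TRUE) {
  if (!length(seed_words)) stop("empty seed word list")
  if (any(tree$type == "classifier" &
          !is.na(tree$cls_name) & tree$cls_name == "in_scope")) {
    stop("tree already has an In-Scope root")
  }
  vocab <- rownames(tree$table$vectors)
  pos <- seed_words[seed_words %in% vocab]
  if (length(pos) < length(seed_words)) {
    warning("skipped out-of-vocabulary seed word(s): ",
            paste(setdiff(seed_words, pos), collapse = ", "))
  }
  if (!length(pos)) stop("all seed words are out of vocabulary")
  neg <- setdiff(stopwords[stopwords %in% vocab], pos)
  if (!length(neg)) stop("no in-vocabulary stopword available as negatives")
  model <- train_margin_classifier(
    tree$table$vectors[pos, , drop = FALSE],
    tree$table$vectors[neg, , drop = FALSE], cost = cost)
  old_root <- tree$root
  cid <- add_node(tree, "classifier", 0L, 0L)
  bid <- add_node(tree, "bin", cid, 1L)
  tree$cls_name[cid] <- "in_scope"
  tree$cls_pos[[cid]] <- pos
  tree$cls_neg[[cid]] <- neg
  tree$cls_model[[cid]] <- model
  tree$cls_seeded[cid] <- TRUE
  tree$left[cid] <- old_root
  tree$right[cid] <- bid
  tree$parent[old_root] <- cid
  tree$root <- cid
  recompute_depths(tree)
  if (rebuild) rebuild_tree(tree, retrain = FALSE)
  invisible(tree)
}

# nearest classifier ancestor reached through an accept edge; 0 = tree top.
# Chain links (reject edges between classifiers at the same level) are
# skipped so classifiers sharing a level share an owner.
classifier_owner <- function(tree, id) {
  cur <- id
  p <- tree$parent[cur]
  while (p != 0L) {
    if (tree$type[p] == "classifier" && tree$left[p] == cur) return(p)
    cur <- p
    p <- tree$parent[cur]
  }
  0L
}

#' Attach a topic classifier to the tree
#'
#' Inserts a named classifier node near the top of the tree: under the
#' nearest classifier ancestor of the targeted clustering node (or above
#' the clustering root when there is none).  The new classifier gets a
#' fresh, empty clustering child for the documents it accepts, while the
#' subtree it displaced becomes its clustering brother, receiving the
#' documents it rejects.  Attaching under an existing classifier's child
#' creates a subtopic classifier.  With empty training sets the node is
#' inactive (it passes everything to the brother) until it has at least
#' one positive and one negative id and the tree is rebuilt.
#'
#' @param tree A `topic_tree`.
#' @param target_node_id The clustering node whose neighborhood motivated
#'   the topic (determines where the classifier is inserted).
#' @param name Unique topic label.
#' @param positive_ids,negative_ids Document ids to train from.
#' @return The new classifier's node id, invisibly.
#' @export
attach_classifier <- function(tree, target_node_id, name,
                              positive_ids = character(),
                              negative_ids = character()) {
  check_cluster(tree, target_node_id)
  if (name %in% tree$cls_name[!is.na(tree$cls_name)]) {
    stop("classifier name collision: ", name)
  }
  bad <- setdiff(c(positive_ids, negative_ids), tree$docs$ids)
  if (length(bad)) stop("unknown training document id(s): ",
                        paste(head(bad, 5), collapse = ", "))
  if (length(intersect(positive_ids, negative_ids))) {
    stop("positive and negative training ids must be disjoint")
  }
  owner <- classifier_owner(tree, target_node_id)
  displaced <- if (owner == 0L) tree$root else tree$left[owner]
  cid <- add_node(tree, "classifier", owner, 0L)
  child <- add_node(tree, "cluster", cid, 0L)
  tree$cls_name[cid] <- name
  tree$cls_pos[[cid]] <- positive_ids
  tree$cls_neg[[cid]] <- negative_ids
  tree$left[cid] <- child
  tree$right[cid] <- displaced
  tree$parent[displaced] <- cid
  if (owner == 0L) tree$root <- cid else tree$left[owner] <- cid
  recompute_depths(tree)
  invisible(cid)
}

#' Effective training sets under sibling augmentation
#'
#' A classifier can enlarge its training set with instances of the
#' surrounding classifiers: the positives of its siblings (classifiers
#' sharing the same parent classifier, or the tree top) are added to its
#' negatives, excluding any id already among its own positives.
#'
#' @param tree A `topic_tree`.
#' @param name Classifier name.
#' @return List with `positive_ids` and `negative_ids`.
#' @export
augment_training <- function(tree, name) {
  cid <- which(!is.na(tree$cls_name) & tree$cls_name == name)
  if (!length(cid)) stop("unknown classifier: ", name)
  pos <- tree$cls_pos[[cid]]
  neg <- tree$cls_neg[[cid]]
  own <- classifier_owner(tree, cid)
  sibs <- setdiff(which(tree$type == "classifier" & !tree$cls_seeded), cid)
  sibs <- sibs[vapply(sibs, function(s) classifier_owner(tree, s) == own,
                      logical(1))]
  extra <- setdiff(unique(unlist(tree$cls_pos[sibs])), pos)
  list(positive_ids = pos, negative_ids = union(neg, extra))
}

train_classifier_node <- function(tree, cid, augment = FALSE, cost = 1) {
  if (tree$cls_seeded[cid]) return(invisible(tree))  # seed-word root
  sets <- if (augment) augment_training(tree, tree$cls_name[cid])
          else list(positive_ids = tree$cls_pos[[cid]],
                    negative_ids = tree$cls_neg[[cid]])
  pos <- match(sets$positive_ids, tree$docs$ids)
  neg <- match(sets$negative_ids, tree$docs$ids)
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) {
    tree$cls_model[cid] <- list(NULL)  # inactive until trainable
    return(invisible(tree))
  }
  tree$cls_model[[cid]] <- train_margin_classifier(
    tree$docs$vectors[pos, , drop = FALSE],
    tree$docs$vectors[neg, , drop = FALSE], cost = cost)
  invisible(tree)
}

#' Retrain classifiers and re-stream the corpus
#'
#' Retrains every trainable classifier node from its current training
#' ids (optionally with sibling augmentation) and runs one full streaming
#' pass so every document is re-routed through the updated filters, with
#' headwords refreshed at pass end.
#'
#' @param tree A `topic_tree`.
#' @param augment Enable sibling-positives-as-negatives augmentation.
#' @param retrain Set to `FALSE` to re-stream without touching models.
#' @param cost SVM regularization strength used at retraining.
#' @return The tree, invisibly (modified in place).
#' @export
rebuild_tree <- function(tree, augment = FALSE, retrain = TRUE, cost = 1) {
  if (retrain) {
    for (cid in which(tree$type == "classifier")) {
      train_classifier_node(tree, cid, augment = augment, cost = cost)
    }
  }
  stream_pass(tree)
  invisible(tree)
}

#' Apply labeling feedback to classifier nodes
#'
#' Each event moves a document into the named classifier's positive or
#' negative training set (removing it from the opposite set, so the sets
#' stay disjoint).  Events are idempotent: applying the same event twice
#' changes nothing.  Affected classifiers are retrained and the corpus is
#' re-streamed.
#'
#' @param tree A `topic_tree`.
#' @param events Data frame with columns `doc_id`, `classifier`,
#'   `verdict` (`"positive"` or `"negative"`).
#' @param rebuild Retrain and re-stream after applying (default TRUE).
#' @return The tree, invisibly (modified in place).
#' @export
apply_feedback <- function(tree, events, rebuild = TRUE) {
  stopifnot(all(c("doc_id", "classifier", "verdict") %in% names(events)))
  for (i in seq_len(nrow(events))) {
    nm <- events$classifier[i]
    cid <- which(!is.na(tree$cls_name) & tree$cls_name == nm)
    if (!length(cid)) stop("unknown classifier: ", nm)
    doc <- events$doc_id[i]
    if (!doc %in% tree$docs$ids) stop("unknown document id: ", doc)
    v <- events$verdict[i]
    if (!v %in% c("positive", "negative")) stop("bad verdict: ", v)
    if (v == "positive") {
      tree$cls_pos[[cid]] <- union(tree$cls_pos[[cid]], doc)
      tree$cls_neg[[cid]] <- setdiff(tree$cls_neg[[cid]], doc)
    } else {
      tree$cls_neg[[cid]] <- union(tree$cls_neg[[cid]], doc)
      tree$cls_pos[[cid]] <- setdiff(tree$cls_pos[[cid]], doc)
    }
  }
  if (rebuild) rebuild_tree(tree)
  invisible(tree)
}
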