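#' Default English stopword list
#'
#' A compact list of common English function words.  These are removed at
#' tokenization time and, mirroring the interactive workflow, double as the
#' predefined negative training examples of the In-Scope root classifier
#' (see [make_in_scope()]).
#'
#' @return Character vector of lowercase stopwords.
#' @export
stopwords_en <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is",
    "it", "its", "itself", "just", "me", "more", "most", "my", "myself",
    "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "out", "over", "own", "same", "she", "should",
    "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
    "then", "there", "these", "they", "this", "those", "through", "to",
    "too", "under", "until", "up", "very", "was", "we", "were", "what",
    "when", "where", "which", "while", "who", "whom", "why", "will",
    "with", "would", "you", "your", "yours")
}

#' Tokenize a text string
#'
#' Lowercases, strips all non-alphanumeric characters, splits on
#' whitespace and removes stopwords.  Token order and multiplicity are
#' preserved; the result may be empty (empty documents are rejected later,
#' at vectorization).
#'
#' @param text Character string (length-1).
#' @param stopwords Character vector of tokens to drop; use `character()`
#'   to keep everything.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Type 2 Diabetes.", stopwords = character())
#' @export
tokenize <- function(text, stopwords = stopwords_en()) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(stopwords)) toks <- toks[!toks %in% stopwords]
  toks
}

#' Construct an embedding table from a numeric matrix
#'
#' @param mat Numeric matrix, one row per token; rownames are the tokens.
#' @return An `embedding_table`: the raw vectors, their row-normalized
#'   counterparts (cached for cosine work) and the dimension.
#' @export
embedding_table <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate tokens in embedding table")
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    stop("zero vector(s) for token(s): ",
         paste(rownames(mat)[norms == 0], collapse = ", "))
  }
  structure(list(vectors = mat, unit = mat / norms, dim = ncol(mat)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Number of tokens in an embedding table
#' @param table An `embedding_table`.
#' @export
vocab_size <- function(table) nrow(table$vectors)

#' Read word embeddings in word2vec text format
#'
#' The file starts with a header line `"<count> <dim>"` followed by one
#' line per token: the token and `dim` floats, space-separated.  Plain or
#' gzip-compressed files are accepted.  Tokens mapping to the all-zero
#' vector are rejected (dropped with a warning naming them): downstream
#' cosine arithmetic is undefined for them.
#'
#' @param path Path to the embeddings file.
#' @param vocabulary Optional character vector; when given, the table is
#'   restricted to these tokens (typically the corpus vocabulary, which
#'   keeps per-node accumulators small).
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stop("embeddings file not found: ", path)
  lines <- readLines(path)  # file()/readLines decompress .gz transparently
  if (!length(lines)) stop("empty embeddings file: ", path)
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed word2vec header (expected 'count dim'): line 1")
  }
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    warning(sprintf("header declares %d tokens but file has %d data lines",
                    n, length(body)))
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  len <- lengths(parts)
  bad <- which(len != d + 1L)
  if (length(bad)) {
    stop(sprintf("malformed embedding line %d: expected %d fields, got %d",
                 bad[1] + 1L, d + 1L, len[bad[1]]))
  }
  tokens <- vapply(parts, `[`, character(1), 1L)
  keep <- rep(TRUE, length(tokens))
  if (!is.null(vocabulary)) keep <- tokens %in% vocabulary
  if (!any(keep)) stop("no embedding token matches the vocabulary filter")
  parts <- parts[keep]; tokens <- tokens[keep]
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    stop(sprintf("non-numeric value on embedding line for token '%s'",
                 tokens[bad]))
  }
  mat <- t(vals)
  rownames(mat) <- tokens
  zero <- rowSums(mat^2) == 0
  if (any(zero)) {
    warning("rejected zero-vector token(s): ",
            paste(tokens[zero], collapse = ", "))
    mat <- mat[!zero, , drop = FALSE]
  }
  if (!nrow(mat)) stop("no usable embedding vectors in ", path)
  embedding_table(mat)
}

#' Write an embedding table in word2vec text format
#'
#' @param table An [embedding_table()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_embeddings <- function(table, path) {
  mat <- table$vectors
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  rows <- apply(mat, 1, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE, digits = 15),
          collapse = " "))
  writeLines(paste(rownames(mat), rows), con)
  invisible(path)
}

#' Read a line-delimited corpus
#'
#' One JSON object per line with fields `id`, `text` and optionally
#' `label` (a gold topic code).  Plain or gzip-compressed.
#'
#' @param path Path to the corpus file.
#' @return A `corpus` data.frame with columns `id`, `text`, `label`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) stop(sprintf(
                    "malformed corpus record on line %d: %s",
                    i, conditionMessage(e)), call. = FALSE))
    if (is.null(r$id) || is.null(r$text)) {
      stop(sprintf("corpus record on line %d lacks id/text", i))
    }
    data.frame(id = as.character(r$id), text = as.character(r$text),
               label = if (is.null(r$label)) NA_character_
                       else as.character(r$label),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$id)) stop("duplicate document ids in ", path)
  class(out) <- c("corpus", class(out))
  out
}

#' Write a corpus as line-delimited JSON
#'
#' @param corpus Data frame with columns `id`, `text` and optional `label`.
#' @param path Output path; `.gz` triggers compression.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(all(c("id", "text") %in% names(corpus)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  has_label <- "label" %in% names(corpus) && !all(is.na(corpus$label))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (has_label && !is.na(corpus$label[i])) rec$label <- corpus$label[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Embed a tokenized document as the mean of its word vectors
#'
#' Out-of-vocabulary tokens are skipped; a document with no in-vocabulary
#' token has no vector and is an error.
#'
#' @param tokens Character vector of tokens.
#' @param table An [embedding_table()].
#' @return Numeric vector of length `table$dim`.
#' @export
embed_document <- function(tokens, table) {
  idx <- match(tokens, rownames(table$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("empty document: no token found in the embedding table")
  colMeans(table$vectors[idx, , drop = FALSE])
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Vectorize a corpus against an embedding table
#'
#' Tokenizes every document, drops out-of-vocabulary tokens, and computes
#' mean-embedding document vectors.  Documents left with zero
#' in-vocabulary tokens are dropped with a warning listing their ids.
#'
#' @param corpus A `corpus` data frame (see [read_corpus()]).
#' @param table An [embedding_table()].
#' @param stopwords Stopword list passed to [tokenize()].
#' @return A `document_set`: ids, gold labels, per-document token indices
#'   into the table vocabulary (with multiplicity), the n-by-dim matrix of
#'   mean vectors, and cached per-document token-count summaries used by
#'   the streaming clusterer.
#' @export
vectorize_corpus <- function(corpus, table, stopwords = stopwords_en()) {
  vocab <- rownames(table$vectors)
  tok_idx <- lapply(corpus$text, function(txt) {
    ix <- match(tokenize(txt, stopwords), vocab)
    ix[!is.na(ix)]
  })
  keep <- lengths(tok_idx) > 0L
  if (!all(keep)) {
    warning("dropped ", sum(!keep), " document(s) with no in-vocabulary ",
            "tokens: ", paste(head(corpus$id[!keep], 10), collapse = ", "))
  }
  if (!any(keep)) stop("no document survived vectorization")
  tok_idx <- tok_idx[keep]
  ids <- corpus$id[keep]
  labels <- if ("label" %in% names(corpus)) corpus$label[keep]
            else rep(NA_character_, sum(keep))
  d <- table$dim
  n <- length(ids)
  tok_sums <- matrix(0, n, d)
  u_idx <- vector("list", n)
  u_cnt <- vector("list", n)
  for (i in seq_len(n)) {
    ix <- tok_idx[[i]]
    u <- sort(unique(ix))
    cnt <- tabulate(match(ix, u), nbins = length(u))
    u_idx[[i]] <- u
    u_cnt[[i]] <- cnt
    tok_sums[i, ] <- crossprod(table$vectors[u, , drop = FALSE], cnt)
  }
  vecs <- tok_sums / lengths(tok_idx)
  structure(list(ids = ids, labels = labels, token_idx = tok_idx,
                 u_idx = u_idx, u_cnt = u_cnt, tok_sums = tok_sums,
                 vectors = vecs, n = n, dim = d,
                 dropped = corpus$id[!keep]),
            class = "document_set")
}

#' @export
print.document_set <- function(x, ...) {
  cat(sprintf("<document_set> %d documents, dimension %d", x$n, x$dim))
  if (any(!is.na(x$labels))) {
    cat(sprintf(", %d labeled", sum(!is.na(x$labels))))
  }
  cat("\n")
  invisible(x)
}

#' Subset a document set
#'
#' @param docs A `document_set`.
#' @param i Integer or logical index, or character vector of ids.
#' @return A `document_set` restricted (and reordered) to `i`.
#' @export
subset_docs <- function(docs, i) {
  if (is.character(i)) {
    i <- match(i, docs$ids)
    if (anyNA(i)) stop("unknown document id(s) in subset")
  }
  if (is.logical(i)) i <- which(i)
  structure(list(ids = docs$ids[i], labels = docs$labels[i],
                 token_idx = docs$token_idx[i],
                 u_idx = docs$u_idx[i], u_cnt = docs$u_cnt[i],
                 tok_sums = docs$tok_sums[i, , drop = FALSE],
                 vectors = docs$vectors[i, , drop = FALSE],
                 n = length(i), dim = docs$dim, dropped = character(0)),
            class = "document_set")
}

#' Per-document token strings
#'
#' @param docs A `document_set`.
#' @param table The `embedding_table` the set was vectorized against.
#' @param i Document index or id.
#' @return Character vector of the document's in-vocabulary tokens.
#' @export
doc_tokens <- function(docs, table, i) {
  if (is.character(i)) i <- match(i, docs$ids)
  rownames(table$vectors)[docs$token_idx[[i]]]
}
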