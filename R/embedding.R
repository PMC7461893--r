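# Joint term and document embeddings over tokenized streams. Two backends sit
# behind one narrow interface (streams in, vector table out):
#   * "sgns": an iterative skip-gram negative-sampling trainer (Rcpp) that
#     also trains document vectors dbow-style, honouring the window size,
#     epoch count and the linear learning-rate schedule;
#   * "ppmi_svd": a deterministic count-based backend (positive pointwise
#     mutual information over window co-occurrences, truncated SVD), with
#     document vectors as the mean of their tokens' term vectors.
# Both respect min_count; terms below it get no vector.

#' Embedding configuration
#'
#' Defaults follow common practice for literature-scale corpora: window 7,
#' 300 dimensions, minimum term count 10, 10 epochs, learning rate 0.025
#' reduced by 0.002 per epoch (floored at 1e-4).
#'
#' @param window Context window size (tokens each side).
#' @param dimension Vector dimensionality (>= 2).
#' @param min_count Minimum total stream count for a term to receive a vector.
#' @param epochs Training epochs (iterative backends).
#' @param initial_learning_rate,learning_rate_decay_per_epoch Linear
#'   learning-rate schedule; the per-epoch rate is
#'   `max(initial - k * decay, 1e-4)` at (0-based) epoch `k`.
#' @param train_word_vectors Train term vectors (must be `TRUE` for term
#'   clustering; document-only training is supported for completeness).
#' @param random_seed Integer seed; fixed seed + single-threaded training
#'   gives a reproducible table.
#' @param backend `"ppmi_svd"` (default; deterministic count-based) or
#'   `"sgns"` (iterative).
#' @param negative Number of negative samples per positive pair (sgns).
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(window = 7L, dimension = 300L, min_count = 10L,
                             epochs = 10L, initial_learning_rate = 0.025,
                             learning_rate_decay_per_epoch = 0.002,
                             train_word_vectors = TRUE, random_seed = 1L,
                             backend = c("ppmi_svd", "sgns"), negative = 5L) {
  backend <- match.arg(backend)
  stopifnot(dimension >= 2L, epochs >= 1L, window >= 1L, min_count >= 0L,
            initial_learning_rate > 0, learning_rate_decay_per_epoch >= 0)
  structure(list(window = as.integer(window), dimension = as.integer(dimension),
                 min_count = as.integer(min_count), epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 learning_rate_decay_per_epoch = learning_rate_decay_per_epoch,
                 train_word_vectors = isTRUE(train_word_vectors),
                 random_seed = as.integer(random_seed), backend = backend,
                 negative = as.integer(negative)),
            class = "embedding_config")
}

new_vector_table <- function(term_vectors, doc_vectors) {
  structure(list(term_vectors = term_vectors, doc_vectors = doc_vectors,
                 dimension = ncol(term_vectors)),
            class = "vector_table")
}

#' Train term and document vectors
#'
#' @param streams Named list of `token_stream` objects (names are article ids).
#' @param config An [embedding_config()].
#' @return A `vector_table`: list with `term_vectors` (matrix, one row per
#'   term id with total count >= `min_count`) and `doc_vectors` (one row per
#'   article).
#' @export
train_embeddings <- function(streams, config = embedding_config()) {
  if (length(streams) == 0L) stop_semkos("streams must be non-empty")
  counts <- corpus_term_counts(streams)
  vocab <- names(counts)[counts >= config$min_count]
  if (length(vocab) == 0L)
    stop_semkos("no term reaches min_count = ", config$min_count,
                "; lower min_count or enlarge the corpus")
  vocab <- sort(vocab)
  doc_ids <- names(streams) %||%
    vapply(streams, function(s) attr(s, "article_id"), character(1))
  seqs <- lapply(streams, function(s) {
    i <- match(s$term_id, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  if (config$backend == "sgns") {
    fit <- .sgns_train(seqs, length(vocab), config$dimension, config$window,
                       config$epochs, config$initial_learning_rate,
                       config$learning_rate_decay_per_epoch, config$negative,
                       config$train_word_vectors,
                       as.double(config$random_seed))
    tm <- fit$term_vectors; dm <- fit$doc_vectors
  } else {
    fit <- ppmi_svd_train(seqs, length(vocab), config)
    tm <- fit$term_vectors; dm <- fit$doc_vectors
  }
  rownames(tm) <- vocab
  rownames(dm) <- doc_ids
  new_vector_table(tm, dm)
}

# Count-based backend: window co-occurrence -> PPMI -> truncated SVD.
# Deterministic (sign of each singular vector fixed by its largest component).
ppmi_svd_train <- function(seqs, n_vocab, config) {
  # accumulate symmetric window co-occurrence counts: gather all ordered
  # pair indices, then tabulate once
  pair_idx <- lapply(seqs, function(s) {
    n <- length(s)
    if (n < 2L) return(integer(0))
    unlist(lapply(seq_len(min(config$window, n - 1L)), function(d) {
      a <- s[seq_len(n - d)] + 1L
      b <- s[seq.int(d + 1L, n)] + 1L
      c((b - 1L) * n_vocab + a, (a - 1L) * n_vocab + b)
    }), use.names = FALSE)
  })
  co <- matrix(tabulate(unlist(pair_idx, use.names = FALSE),
                        nbins = n_vocab * n_vocab), n_vocab, n_vocab)
  total <- sum(co)
  if (total == 0) {
    # no co-occurrence at all: fall back to tiny deterministic vectors
    tm <- matrix(1e-6, n_vocab, config$dimension)
  } else {
    pr <- rowSums(co) / total
    pc <- colSums(co) / total
    pmi <- log(pmax(co / total, .Machine$double.xmin) /
                 pmax(outer(pr, pc), .Machine$double.xmin))
    pmi[co == 0] <- 0
    pmi[pmi < 0] <- 0
    sv <- svd(pmi, nu = min(config$dimension, n_vocab), nv = 0)
    k <- min(config$dimension, ncol(sv$u))
    tm <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(sv$d[seq_len(k)]), k, k)
    # deterministic sign convention
    for (j in seq_len(k)) {
      i <- which.max(abs(tm[, j]))
      if (tm[i, j] < 0) tm[, j] <- -tm[, j]
    }
    if (k < config$dimension)
      tm <- cbind(tm, matrix(0, n_vocab, config$dimension - k))
  }
  dm <- t(vapply(seqs, function(s) {
    if (length(s) == 0L) return(rep(0, config$dimension))
    colMeans(tm[s + 1L, , drop = FALSE])
  }, numeric(config$dimension)))
  list(term_vectors = tm, doc_vectors = dm)
}

#' Unit-normalize term vectors
#'
#' Divides every term vector by its Euclidean norm (document vectors are left
#' untouched). Errors on a zero-norm term vector, naming the term.
#'
#' @param table A `vector_table`.
#' @return The normalized `vector_table`.
#' @export
normalize_vectors <- function(table) {
  norms <- sqrt(rowSums(table$term_vectors^2))
  zero <- norms == 0
  if (any(zero))
    stop_semkos("zero-norm term vector(s): ",
                paste(rownames(table$term_vectors)[zero], collapse = ", "))
  table$term_vectors <- table$term_vectors / norms
  table
}

#' Write / read vectors in word2vec text format
#'
#' Header line `count dim`, then one `id v1 ... vd` line per vector.
#'
#' @param m Matrix with rownames (ids).
#' @param path File path.
#' @return `write_word2vec_text()` returns `path` invisibly;
#'   `read_word2vec_text()` the matrix.
#' @export
write_word2vec_text <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(sprintf("%.17g", m[i, ]), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_word2vec_text
#' @export
read_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(m) <- vapply(parts, `[`, character(1), 1L)
  m
}
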