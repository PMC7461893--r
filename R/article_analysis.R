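# Article-group analysis: retrieve articles by KOS cluster, cluster document
# vectors with multi-round affinity propagation, and profile groups through
# coverage vectors (per term cluster, the fraction of the group's articles
# containing at least one member term) and coverage differences.

#' Retrieve the articles covering a KOS cluster
#'
#' An article belongs to the group iff its token stream contains at least one
#' member term of the named level-2 cluster.
#'
#' @param kos A `kos`.
#' @param name Level-2 annotation name.
#' @param streams Named list of `token_stream` objects.
#' @return An `article_group`: list with `group_id` and `members` (article
#'   ids, each once); attribute `cluster` records the retrieval cluster.
#' @export
retrieve_articles <- function(kos, name, streams) {
  members <- kos_members(kos, name)
  if (length(members) == 0L) stop_semkos("empty cluster: ", name)
  hit <- vapply(streams, function(s) any(s$term_id %in% members), logical(1))
  ids <- vapply(streams[hit], function(s) attr(s, "article_id"), character(1))
  structure(list(group_id = name, members = unique(unname(ids))),
            cluster = name, class = "article_group")
}

#' Affinity propagation clustering
#'
#' Frey-Dueck responsibility/availability message passing with pinned
#' settings: similarity is negative squared Euclidean distance, the shared
#' preference is the median similarity (over the full similarity matrix,
#' whose diagonal is zero — the convention of the reference library
#' implementations), damping 0.5, at most `max_iter` iterations, convergence
#' declared when the exemplar set is stable for `convergence_iter`
#' iterations. The algorithm has no internal randomness, so identical inputs
#' give identical outputs.
#'
#' @param vectors Numeric matrix, one row per unit (rownames are unit ids).
#' @param damping Damping factor in `[0.5, 1)`.
#' @param max_iter,convergence_iter Iteration controls.
#' @param preference Optional scalar preference; default median similarity.
#' @return List with `labels` (exemplar row index per unit, named by unit
#'   id), `exemplars` (row indices), `converged` (logical), `iterations`.
#' @export
affinity_propagation <- function(vectors, damping = 0.5, max_iter = 200L,
                                 convergence_iter = 15L, preference = NULL) {
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 2L) stop_semkos("need at least 2 units to cluster")
  sq <- rowSums(X^2)
  S <- -(outer(sq, sq, "+") - 2 * tcrossprod(X))
  S[S > 0] <- 0  # numerical guard: similarities are -d^2 <= 0
  dimnames(S) <- NULL
  if (max(S) - min(S) == 0) {
    # all points coincide: one cluster, exemplared by the first point
    return(list(labels = setNames(rep(1L, n), rownames(X)), exemplars = 1L,
                converged = TRUE, iterations = 0L))
  }
  diag(S) <- preference %||% median(S)
  # break degeneracies: symmetric inputs make the messages oscillate, so add
  # a tiny input-independent jitter (fixed internal seed keeps the algorithm
  # deterministic for identical inputs)
  S <- S + with_seed(0, matrix(stats::rnorm(n * n), n, n)) *
    (max(S) - min(S)) * 1e-9
  R <- A <- matrix(0, n, n)
  E_old <- rep(FALSE, n)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), i1)]
    AS[cbind(seq_len(n), i1)] <- -Inf
    m2 <- AS[cbind(seq_len(n), max.col(AS, ties.method = "first"))]
    Mx <- matrix(m1, n, n)
    Mx[cbind(seq_len(n), i1)] <- m2
    R <- damping * R + (1 - damping) * (S - Mx)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    Anew <- matrix(colSums(Rp), n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    E <- diag(A) + diag(R) > 0
    if (identical(E, E_old)) stable <- stable + 1L else stable <- 0L
    E_old <- E
    if (stable >= convergence_iter && any(E)) { converged <- TRUE; break }
  }
  exemplars <- as.integer(which(diag(A) + diag(R) > 0))
  if (length(exemplars) == 0L)  # degenerate (e.g. all points identical)
    exemplars <- as.integer(which.max(diag(A) + diag(R)))
  labels <- exemplars[max.col(S[, exemplars, drop = FALSE],
                              ties.method = "first")]
  labels[exemplars] <- exemplars  # exemplars are fixed points
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning last-iteration labels")
  list(labels = setNames(labels, rownames(X)), exemplars = exemplars,
       converged = converged, iterations = it)
}

#' Multi-round affinity propagation
#'
#' Round 1 clusters the article vectors; each later round clusters the
#' exemplar vectors of the previous round (exemplars are the algorithm's
#' native representatives). Stops early, with a note, if a round yields a
#' single cluster. The top-level assignment of each article is obtained by
#' composing the rounds.
#'
#' @param doc_vectors Numeric matrix of document vectors (rownames = article
#'   ids).
#' @param rounds Number of rounds (>= 1).
#' @param ... Passed to [affinity_propagation()].
#' @return A `cluster_rounds` list: `rounds` (per-round results including
#'   `n_clusters`), `assignment` (named top-level cluster index per article).
#' @export
multiround_cluster <- function(doc_vectors, rounds = 3L, ...) {
  stopifnot(rounds >= 1L)
  X <- as.matrix(doc_vectors)
  out <- list()
  assignment <- seq_len(nrow(X))  # index into current round's units
  for (r in seq_len(rounds)) {
    if (nrow(X) < 2L) {
      message("round ", r, ": fewer than 2 units; stopping early")
      break
    }
    fit <- affinity_propagation(X, ...)
    out[[r]] <- list(labels = fit$labels, exemplars = fit$exemplars,
                     converged = fit$converged,
                     n_clusters = length(fit$exemplars))
    # map previous assignment through this round's labels
    exemplar_index <- match(fit$labels, fit$exemplars)
    assignment <- exemplar_index[assignment]
    if (length(fit$exemplars) == 1L) {
      if (r < rounds) message("round ", r, ": single cluster; stopping early")
      X <- X[fit$exemplars, , drop = FALSE]
      break
    }
    X <- X[fit$exemplars, , drop = FALSE]
  }
  structure(list(rounds = out,
                 assignment = setNames(assignment, rownames(doc_vectors))),
            class = "cluster_rounds")
}

#' Coverage vector of an article group
#'
#' For each level-2 term cluster, the fraction of the group's articles that
#' contain at least one member term ("cover" the cluster).
#'
#' @param group An `article_group` (or character vector of article ids).
#' @param streams Named list of `token_stream` objects.
#' @param kos A `kos`.
#' @return Named numeric vector in `[0, 1]`, one entry per level-2 cluster.
#' @export
coverage_vector <- function(group, streams, kos) {
  ids <- if (inherits(group, "article_group")) group$members else group
  if (length(ids) == 0L) stop_semkos("empty article group")
  tmap <- kos_term_map(kos)
  l2 <- kos_level2_names(kos)
  # clusters covered per article
  hit <- matrix(FALSE, length(ids), length(l2), dimnames = list(ids, l2))
  for (id in ids) {
    s <- streams[[id]]
    if (is.null(s)) next
    covered <- unique(tmap[s$term_id])
    covered <- covered[!is.na(covered)]
    hit[id, covered] <- TRUE
  }
  colMeans(hit)
}

#' Coverage difference vector
#'
#' Subgroup coverage minus reference coverage, per level-2 cluster; positive
#' entries are what the subgroup over-represents.
#'
#' @param subgroup,reference `article_group` objects (or id vectors).
#' @param streams Named list of `token_stream` objects.
#' @param kos A `kos`.
#' @return Named numeric vector in `[-1, 1]`.
#' @export
coverage_difference <- function(subgroup, reference, streams, kos) {
  coverage_vector(subgroup, streams, kos) -
    coverage_vector(reference, streams, kos)
}

#' Profile an article group against the KOS
#'
#' Ranks the top-k keyword clusters and top-k method clusters by coverage
#' (or by coverage difference when a `reference` group is supplied), and
#' retrieves the k most-cited member articles. The retrieval cluster itself
#' is excluded by default (it trivially covers the whole group).
#'
#' @param group An `article_group`.
#' @param streams Named list of `token_stream` objects.
#' @param kos_kwd,kos_mtd Keyword and method `kos` objects.
#' @param citations Named numeric vector `article_id -> citations`.
#' @param k List length (default 10).
#' @param reference Optional reference `article_group` for coverage
#'   differences.
#' @param exclude Cluster names excluded from the rankings; defaults to the
#'   group's retrieval cluster, if recorded.
#' @return List with data frames `keywords` and `methods` (columns `name`,
#'   `value`, descending, index tie-break) and `top_cited` (columns
#'   `article_id`, `citations`).
#' @export
profile_article_group <- function(group, streams, kos_kwd, kos_mtd, citations,
                                  k = 10L, reference = NULL,
                                  exclude = attr(group, "cluster")) {
  rank_one <- function(kos) {
    v <- if (is.null(reference)) coverage_vector(group, streams, kos)
         else coverage_difference(group, reference, streams, kos)
    keep <- !(names(v) %in% exclude)
    v <- v[keep]
    o <- order(-v, seq_along(v))
    o <- o[seq_len(min(k, length(o)))]
    data.frame(name = names(v)[o], value = unname(v[o]),
               stringsAsFactors = FALSE)
  }
  cit <- citations[group$members]
  cit[is.na(cit)] <- 0
  o <- order(-cit, group$members)
  o <- o[seq_len(min(k, length(o)))]
  list(keywords = rank_one(kos_kwd), methods = rank_one(kos_mtd),
       top_cited = data.frame(article_id = group$members[o],
                              citations = as.numeric(cit[o]),
                              stringsAsFactors = FALSE))
}

#' Write a group profile as TSV
#'
#' Mirrors a two-block layout (`ID`, `Cluster name`, `Coverage`), coverage as
#' percentages with two decimals.
#'
#' @param profile Result of [profile_article_group()].
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  fmt <- function(df, block) {
    data.frame(block = block, name = df$name,
               coverage = sprintf("%.2f%%", 100 * df$value),
               stringsAsFactors = FALSE)
  }
  out <- rbind(fmt(profile$keywords, "keyword"),
               fmt(profile$methods, "method"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("block", "Cluster name", "Coverage"),
              fileEncoding = "UTF-8")
  invisible(path)
}
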