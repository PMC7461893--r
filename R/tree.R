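# Average-linkage (UPGMA) agglomeration over unit-normalized term vectors.
# Node labelling convention: leaves are 1..n (in term order); the k-th merge
# creates node n+k, so the root is 2n-1. Heights are the average inter-cluster
# distances at merge time and are non-decreasing (average linkage is
# reducible). Tie-break when two pairs share the minimal average distance:
# merge the pair with the smallest (min label, max label) lexicographic key.

#' Pairwise Euclidean distances between term vectors
#'
#' On unit-norm vectors Euclidean distance is a monotone transform of cosine
#' distance (d = sqrt(2 - 2 cos)).
#'
#' @param table A `vector_table` with normalized term vectors.
#' @param term_ids Terms to include (default: all).
#' @return A symmetric `dist_matrix` (matrix with zero diagonal, dimnames =
#'   term ids).
#' @export
pairwise_distances <- function(table, term_ids = rownames(table$term_vectors)) {
  missing <- setdiff(term_ids, rownames(table$term_vectors))
  if (length(missing))
    stop_semkos("unknown term_id(s): ", paste(missing, collapse = ", "))
  v <- table$term_vectors[term_ids, , drop = FALSE]
  g <- tcrossprod(v)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, class = c("dist_matrix", class(d)))
}

new_merge_tree <- function(n_leaves, leaf_labels, merges) {
  structure(list(n_leaves = as.integer(n_leaves),
                 leaf_labels = as.character(leaf_labels),
                 merges = merges),
            class = "merge_tree")
}

#' Average-linkage agglomerative clustering with explicit node labels
#'
#' At each step the pair of active clusters with the minimal average
#' inter-cluster distance is merged; the k-th created node is labelled
#' `n + k` and its height is that average distance. Ties are broken by the
#' smallest `(min label, max label)` key of the candidate pair.
#'
#' @param d A symmetric distance matrix (`dist_matrix` or plain matrix) with
#'   zero diagonal; its dimnames (if any) become the leaf labels.
#' @return A `merge_tree`: `n_leaves`, `leaf_labels` (term ids for leaves
#'   1..n), and `merges`, a data frame with columns `a`, `b` (child node
#'   labels, `a < b`) and `height`, in merge order.
#' @export
agglomerate_average_linkage <- function(d) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n < 2L) stop_semkos("need at least 2 items to cluster")
  leaf_labels <- rownames(d) %||% as.character(seq_len(n))
  # sums[i,j] = sum of original pairwise distances between members of active
  # clusters i and j; average = sums / (size_i * size_j). Updated additively,
  # which keeps it exactly the sum an all-pairs recomputation would use.
  sums <- d
  size <- rep(1L, n)
  label <- seq_len(n)
  active <- rep(TRUE, n)
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L))
  for (k in seq_len(n - 1L)) {
    idx <- which(active)
    avg <- sums[idx, idx, drop = FALSE] /
      outer(size[idx], size[idx])
    diag(avg) <- Inf
    best <- min(avg)
    cand <- which(avg == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break on (min label, max label) of the pair
    la <- pmin(label[idx[cand[, 1]]], label[idx[cand[, 2]]])
    lb <- pmax(label[idx[cand[, 1]]], label[idx[cand[, 2]]])
    pick <- order(la, lb)[1]
    i <- idx[cand[pick, 1]]; j <- idx[cand[pick, 2]]
    merges$a[k] <- min(label[i], label[j])
    merges$b[k] <- max(label[i], label[j])
    merges$height[k] <- best
    # merge j into i
    others <- setdiff(idx, c(i, j))
    sums[i, others] <- sums[i, others] + sums[j, others]
    sums[others, i] <- sums[i, others]
    size[i] <- size[i] + size[j]
    label[i] <- n + k
    active[j] <- FALSE
  }
  new_merge_tree(n, leaf_labels, merges)
}

#' Validate merge-tree invariants
#'
#' Checks that node labels are exactly `1..2n-1`, both children of every merge
#' precede their parent, every non-root node has exactly one parent, and
#' heights are non-decreasing in merge order.
#'
#' @param tree A `merge_tree`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_merge_tree <- function(tree) {
  n <- tree$n_leaves
  m <- tree$merges
  if (nrow(m) != n - 1L) stop_semkos("expected ", n - 1L, " merges")
  children <- c(m$a, m$b)
  if (!setequal(children, seq_len(2L * n - 2L)) ||
      anyDuplicated(children))
    stop_semkos("children must be exactly the labels 1..2n-2, once each")
  parents <- n + seq_len(n - 1L)
  if (any(m$a >= parents) || any(m$b >= parents))
    stop_semkos("child labels must precede the created node label")
  if (any(diff(m$height) < -1e-12))
    stop_semkos("heights must be non-decreasing over merge order")
  invisible(TRUE)
}

children_of <- function(tree, node) {
  k <- node - tree$n_leaves
  c(tree$merges$a[k], tree$merges$b[k])
}

node_height <- function(tree, node) {
  if (node <= tree$n_leaves) 0 else tree$merges$height[node - tree$n_leaves]
}

check_node <- function(tree, node) {
  if (!is.numeric(node) || length(node) != 1L || is.na(node) ||
      node < 1L || node > 2L * tree$n_leaves - 1L)
    stop_semkos("invalid node label: ", node)
  as.integer(node)
}

branch_leaves <- function(tree, node) {
  node <- check_node(tree, node)
  stack <- node
  leaves <- integer()
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= tree$n_leaves) leaves <- c(leaves, x)
    else stack <- c(stack, children_of(tree, x))
  }
  sort(leaves)
}

#' Terms under a tree node
#'
#' @param tree A `merge_tree`.
#' @param node A node label (leaf `1..n` or internal `n+1..2n-1`).
#' @return Character vector of term ids of all leaves under `node`, in leaf
#'   label order.
#' @export
branch_terms <- function(tree, node) {
  tree$leaf_labels[branch_leaves(tree, node)]
}

#' Sample representative terms of a branch for manual review
#'
#' Supports the branch-review workflow: rather than reading every term under a
#' node, a curator checks a few representatives. Starting from the node's
#' children, the subtree whose top split is highest (coarsest) is repeatedly
#' expanded until `budget` subtrees are on the list; one leaf is then drawn
#' from each subtree (seeded, deterministic). If the budget covers the branch,
#' all its terms are returned.
#'
#' @param tree A `merge_tree`.
#' @param node Branch node label.
#' @param budget Maximum number of terms to return (>= 1).
#' @param seed Integer seed for the within-subtree draws.
#' @return Character vector of term ids.
#' @export
sample_branch_for_review <- function(tree, node, budget, seed = 1L) {
  node <- check_node(tree, node)
  stopifnot(budget >= 1L)
  all_leaves <- branch_leaves(tree, node)
  if (budget >= length(all_leaves)) return(tree$leaf_labels[all_leaves])
  nodes <- node
  repeat {
    internal <- nodes[nodes > tree$n_leaves]
    if (length(nodes) >= budget || length(internal) == 0L) break
    hts <- vapply(internal, function(x) node_height(tree, x), numeric(1))
    expand <- internal[order(-hts, internal)][1]
    nodes <- c(setdiff(nodes, expand), children_of(tree, expand))
  }
  nodes <- sort(nodes)[seq_len(min(budget, length(nodes)))]
  with_seed(seed, {
    picks <- vapply(nodes, function(x) {
      lv <- branch_leaves(tree, x)
      lv[sample.int(length(lv), 1L)]
    }, integer(1))
    tree$leaf_labels[sort(picks)]
  })
}

#' Convert a merge tree to an hclust object
#'
#' @param tree A `merge_tree`.
#' @return An object of class `hclust` (usable with [stats::cutree()] etc.).
#' @export
as_hclust <- function(tree) {
  n <- tree$n_leaves
  merge <- cbind(ifelse(tree$merges$a <= n, -tree$merges$a, tree$merges$a - n),
                 ifelse(tree$merges$b <= n, -tree$merges$b, tree$merges$b - n))
  ord <- integer(0)
  stack <- n - 1L  # root merge index
  while (length(stack)) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (k < 0L) ord <- c(ord, -k)
    else stack <- c(stack, merge[k, 2], merge[k, 1])
  }
  structure(list(merge = merge, height = tree$merges$height, order = ord,
                 labels = tree$leaf_labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a merge tree into k clusters
#'
#' Removing the k-1 highest merges leaves k monophyletic branches.
#'
#' @param tree A `merge_tree`.
#' @param k Number of clusters.
#' @return Named integer vector, `term_id -> cluster index (1..k)`.
#' @export
cut_tree <- function(tree, k) {
  cl <- cutree(as_hclust(tree), k = k)
  setNames(as.integer(cl), tree$leaf_labels)
}

#' Convert a merge tree to an ape phylo object
#'
#' Branch lengths are height differences between a node and its parent; node
#' labels carry the tree's own label convention.
#'
#' @param tree A `merge_tree`.
#' @return An object of class `phylo`.
#' @export
merge_tree_phylo <- function(tree) {
  n <- tree$n_leaves
  # internal label n+k -> phylo node id n + (n - k) so the root (k = n-1)
  # receives phylo id n+1
  phylo_id <- function(lab) ifelse(lab <= n, lab, n + (n - (lab - n)))
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (k in seq_len(n - 1L)) {
    parent <- n + k
    for (child in c(tree$merges$a[k], tree$merges$b[k])) {
      r <- r + 1L
      edges[r, ] <- c(phylo_id(parent), phylo_id(child))
      elen[r] <- tree$merges$height[k] - node_height(tree, child)
    }
  }
  node_label <- character(n - 1L)
  for (k in seq_len(n - 1L)) node_label[phylo_id(n + k) - n] <- as.character(n + k)
  phy <- structure(list(edge = edges, edge.length = elen,
                        tip.label = tree$leaf_labels, node.label = node_label,
                        Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Export a merge tree
#'
#' Formats: `"newick"` (with branch lengths = height differences and internal
#' node labels), `"json"` (round-trips exactly through [import_tree_json()]),
#' and `"indented-text"` (one line per node, `2n-1` lines, children indented
#' under their parent).
#'
#' @param tree A `merge_tree`.
#' @param format One of `"newick"`, `"json"`, `"indented-text"`.
#' @return A character string.
#' @export
export_tree <- function(tree, format = c("newick", "json", "indented-text")) {
  if (!is.character(format) || !format[1] %in% c("newick", "json", "indented-text"))
    stop_semkos("unknown tree export format: ", format[1])
  format <- format[1]
  if (format == "newick") {
    ape::write.tree(merge_tree_phylo(tree))
  } else if (format == "json") {
    as.character(jsonlite::toJSON(
      list(n_leaves = tree$n_leaves, leaf_labels = tree$leaf_labels,
           merges = tree$merges),
      auto_unbox = TRUE, digits = NA))
  } else {
    lines <- character(0)
    walk <- function(node, depth) {
      ind <- strrep("  ", depth)
      if (node <= tree$n_leaves) {
        lines[[length(lines) + 1L]] <<-
          paste0(ind, node, "\t", tree$leaf_labels[node])
      } else {
        lines[[length(lines) + 1L]] <<-
          paste0(ind, node, "\th=", format(node_height(tree, node), digits = 10))
        for (ch in children_of(tree, node)) walk(ch, depth + 1L)
      }
    }
    walk(2L * tree$n_leaves - 1L, 0L)
    paste(lines, collapse = "\n")
  }
}

#' Import a merge tree from its JSON export
#'
#' @param json JSON text produced by `export_tree(tree, "json")`.
#' @return A `merge_tree`.
#' @export
import_tree_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_merge_tree(x$n_leaves, x$leaf_labels,
                 data.frame(a = as.integer(x$merges$a),
                            b = as.integer(x$merges$b),
                            height = as.numeric(x$merges$height)))
}
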