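# The KOS layer: named cluster annotations over merge-tree nodes. Level-2
# annotations are the working clusters (disjoint on terms; a name may span
# several sibling monophyletic branches -- the paraphyletic-union rule).
# Level-3 groups are obtained by re-clustering the level-2 cluster
# representations (mean member unit vectors). Every annotation event is
# recorded on an append-only log so a manual review session is replayable.

#' Create an empty KOS over a merge tree
#'
#' @param tree A `merge_tree`.
#' @return A `kos` object (no annotations yet).
#' @export
kos_new <- function(tree) {
  structure(list(tree = tree, annotations = list(),
                 level3_parent = character(0), log = list()),
            class = "kos")
}

kos_log <- function(kos, event) {
  kos$log[[length(kos$log) + 1L]] <- c(list(seq = length(kos$log) + 1L), event)
  kos
}

#' Level-2 annotation names, in annotation order
#' @param kos A `kos`.
#' @return Character vector.
#' @export
kos_level2_names <- function(kos) {
  vapply(kos$annotations, function(a) a$name, character(1))
}

#' Member terms of a named level-2 annotation
#' @param kos A `kos`.
#' @param name Annotation name.
#' @return Character vector of term ids (union of leaves under the
#'   annotation's nodes).
#' @export
kos_members <- function(kos, name) {
  i <- match(name, kos_level2_names(kos))
  if (is.na(i)) stop_semkos("no level-2 annotation named '", name, "'")
  unique(unlist(lapply(kos$annotations[[i]]$node_labels,
                       function(nd) branch_terms(kos$tree, nd))))
}

# term_id -> level-2 name map over all annotations
kos_term_map <- function(kos) {
  nm <- kos_level2_names(kos)
  out <- character(0)
  for (i in seq_along(nm)) {
    members <- kos_members(kos, nm[i])
    out[members] <- nm[i]
  }
  out
}

#' Annotate a cluster (level 2)
#'
#' Attaches a name to one or several tree nodes. Multi-node annotations
#' implement the paraphyletic-union rule: sibling monophyletic branches that
#' belong to one semantic group share a single name. Level-2 annotations must
#' be disjoint on terms; overlaps error, listing the conflicting terms.
#' Re-using an existing name extends that annotation with additional nodes.
#'
#' @param kos A `kos`.
#' @param node_labels Integer vector of tree node labels.
#' @param name Cluster name.
#' @param level Annotation level; only level 2 annotations are created
#'   directly (level 3 comes from [regroup_level3()]).
#' @return The updated `kos`.
#' @export
annotate_cluster <- function(kos, node_labels, name, level = 2L) {
  stopifnot(identical(as.integer(level), 2L))
  node_labels <- vapply(node_labels, function(nd) check_node(kos$tree, nd),
                        integer(1))
  new_terms <- unique(unlist(lapply(node_labels,
                                    function(nd) branch_terms(kos$tree, nd))))
  covered <- kos_term_map(kos)
  clash <- intersect(new_terms, names(covered))
  i <- match(name, kos_level2_names(kos))
  if (!is.na(i))  # extending an existing name: only other names conflict
    clash <- clash[covered[clash] != name]
  if (length(clash))
    stop_semkos("terms already covered by a level-2 annotation: ",
                paste(clash, collapse = ", "))
  if (is.na(i)) {
    kos$annotations[[length(kos$annotations) + 1L]] <-
      list(name = name, node_labels = sort(node_labels), level = 2L)
  } else {
    kos$annotations[[i]]$node_labels <-
      sort(unique(c(kos$annotations[[i]]$node_labels, node_labels)))
  }
  kos_log(kos, list(action = "annotate", name = name,
                    nodes = paste(node_labels, collapse = ",")))
}

#' Cluster representation vector
#'
#' The componentwise mean of the member terms' unit vectors (not
#' re-normalized), used for level-3 regrouping and the landscape layout.
#'
#' @param kos A `kos`.
#' @param name Level-2 annotation name.
#' @param table A `vector_table` with normalized term vectors.
#' @return Numeric vector of length `dimension`.
#' @export
cluster_representation <- function(kos, name, table) {
  members <- kos_members(kos, name)
  if (length(members) == 0L) stop_semkos("empty cluster: ", name)
  missing <- setdiff(members, rownames(table$term_vectors))
  if (length(missing))
    stop_semkos("no vector for member term(s): ", paste(missing, collapse = ", "))
  colMeans(table$term_vectors[members, , drop = FALSE])
}

#' Regroup level-2 clusters into level-3 groups
#'
#' Builds an average-linkage tree over the level-2 cluster representations and
#' cuts it into `k` groups; each level-2 annotation receives exactly one
#' level-3 parent. Default granularity is about 13 level-2 clusters per
#' level-3 group, the curation ratio the workflow targets.
#'
#' @param kos A `kos` with at least 2 level-2 annotations.
#' @param table A `vector_table`.
#' @param k Number of level-3 groups (default `max(2, ceiling(n2 / 13))`).
#' @param names Optional character vector of level-3 group names (length `k`).
#' @return The updated `kos`, with `level3_parent` mapping each level-2 name
#'   to its level-3 group name.
#' @export
regroup_level3 <- function(kos, table, k = NULL, names = NULL) {
  l2 <- kos_level2_names(kos)
  if (length(l2) < 2L) stop_semkos("need at least 2 level-2 annotations")
  reps <- t(vapply(l2, function(nm) cluster_representation(kos, nm, table),
                   numeric(table$dimension)))
  d <- as.matrix(stats::dist(reps))
  rownames(d) <- colnames(d) <- l2
  tr <- agglomerate_average_linkage(d)
  k <- k %||% max(2L, ceiling(length(l2) / 13))
  k <- min(k, length(l2))
  grp <- cut_tree(tr, k)
  if (is.null(names)) names <- paste0("level3_", sort(unique(grp)))
  if (length(names) != length(unique(grp)))
    stop_semkos("need exactly ", length(unique(grp)), " level-3 names")
  kos$level3_parent <- setNames(names[grp[l2]], l2)
  kos$level3_tree <- tr
  kos_log(kos, list(action = "level3", k = k))
}

#' Landscape layout of level-2 clusters
#'
#' One record per level-2 cluster: 2-D coordinates from a pluggable projector
#' (default: first two principal components of the cluster representations),
#' dot area proportional to the cluster's summed article citations, and a
#' color key equal to the level-3 parent.
#'
#' @param kos A `kos`.
#' @param table A `vector_table`.
#' @param citations_per_cluster Named numeric vector, `level-2 name -> total
#'   citations`; missing entries are treated as 0 with a warning.
#' @param projector Function `matrix -> matrix[, 1:2]`; defaults to PCA.
#' @return Data frame with columns `name`, `x`, `y`, `area`, `level3`.
#' @export
layout_landscape <- function(kos, table, citations_per_cluster,
                             projector = NULL) {
  l2 <- kos_level2_names(kos)
  if (length(l2) == 0L) stop_semkos("no level-2 annotations to lay out")
  reps <- t(vapply(l2, function(nm) cluster_representation(kos, nm, table),
                   numeric(table$dimension)))
  coords <- if (!is.null(projector)) {
    projector(reps)
  } else if (nrow(reps) >= 3L) {
    prcomp(reps, center = TRUE)$x[, 1:2, drop = FALSE]
  } else {
    cbind(seq_len(nrow(reps)) - 1, 0)
  }
  cit <- citations_per_cluster[l2]
  if (anyNA(cit)) {
    warning("missing citation totals for: ",
            paste(l2[is.na(cit)], collapse = ", "), "; treated as 0")
    cit[is.na(cit)] <- 0
  }
  lvl3 <- kos$level3_parent[l2]
  lvl3[is.na(lvl3)] <- "unassigned"
  data.frame(name = l2, x = as.numeric(coords[, 1]), y = as.numeric(coords[, 2]),
             area = as.numeric(cit), level3 = unname(lvl3),
             stringsAsFactors = FALSE)
}

#' Build a level-2 KOS template by cutting the tree at k clusters
#'
#' The automatic starting point for curation: cutting the merge tree at `k`
#' yields `k` monophyletic branches, each annotated under a placeholder name
#' (`<prefix>_<node label>`) that a curator later renames.
#'
#' @param tree A `merge_tree`.
#' @param k Number of clusters.
#' @param prefix Name prefix for the placeholder annotations.
#' @return A `kos` with `k` level-2 annotations.
#' @export
kos_from_cut <- function(tree, k, prefix = "cluster") {
  grp <- cut_tree(tree, k)
  ks <- kos_new(tree)
  # find, for each cut group, the tree node whose branch is exactly the group
  leafset_key <- function(leaves) paste(sort(leaves), collapse = ",")
  node_of <- new.env(parent = emptyenv())
  for (nd in seq_len(2L * tree$n_leaves - 1L))
    assign(leafset_key(branch_leaves(tree, nd)), nd, envir = node_of)
  for (g in sort(unique(grp))) {
    leaves <- which(tree$leaf_labels %in% names(grp)[grp == g])
    nd <- get(leafset_key(leaves), envir = node_of)
    ks <- annotate_cluster(ks, nd, paste0(prefix, "_", nd))
  }
  ks
}

#' Write / read KOS annotations as TSV
#'
#' Columns: `name`, `level`, `node_labels` (comma-separated), `level3_parent`.
#'
#' @param kos A `kos`.
#' @param path File path.
#' @param tree A `merge_tree` (needed to rebuild the `kos` on read).
#' @return `write_kos_tsv()` returns `path` invisibly; `read_kos_tsv()` a
#'   `kos`.
#' @export
write_kos_tsv <- function(kos, path) {
  nm <- kos_level2_names(kos)
  df <- data.frame(
    name = nm, level = 2L,
    node_labels = vapply(kos$annotations, function(a)
      paste(a$node_labels, collapse = ","), character(1)),
    level3_parent = ifelse(is.na(kos$level3_parent[nm]), "",
                           kos$level3_parent[nm]),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_kos_tsv
#' @export
read_kos_tsv <- function(path, tree) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  ks <- kos_new(tree)
  for (i in seq_len(nrow(df))) {
    nodes <- as.integer(strsplit(df$node_labels[i], ",", fixed = TRUE)[[1]])
    ks <- annotate_cluster(ks, nodes, df$name[i])
  }
  parents <- df$level3_parent
  if (any(nzchar(parents)))
    ks$level3_parent <- setNames(ifelse(nzchar(parents), parents, NA_character_),
                                 df$name)
  ks
}
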