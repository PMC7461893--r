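# Citation-weighted keyword-cluster x method-cluster correlation. For one
# article with citation weight W, keyword-cluster occurrence counts K_i and
# method-cluster occurrence counts M_j, the per-article contribution is
#   C_ij = W * K_i * M_j / sum_{all i,j} (K_i * M_j),
# so each article with both token kinds distributes exactly its weight W over
# the matrix. Aggregation is the elementwise sum over articles. Counts are
# token occurrences, not distinct terms.

#' Per-article cluster occurrence counts
#'
#' Maps each token of a stream to its level-2 cluster in the keyword and
#' method KOS and counts occurrences. Tokens not covered by any level-2
#' annotation are ignored.
#'
#' @param stream A `token_stream`.
#' @param kwd_kos,mtd_kos `kos` objects over the keyword and method trees.
#' @param W Citation weight of the article (non-negative).
#' @return An `article_cluster_counts` list: `article_id`, `W`, `K` (named
#'   integer vector over keyword clusters), `M` (method clusters).
#' @export
article_cluster_counts <- function(stream, kwd_kos, mtd_kos, W = 0L) {
  stopifnot(W >= 0)
  kmap <- kos_term_map(kwd_kos)
  mmap <- kos_term_map(mtd_kos)
  kc <- kmap[stream$term_id]; kc <- kc[!is.na(kc)]
  mc <- mmap[stream$term_id]; mc <- mc[!is.na(mc)]
  tab <- function(x) {
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  structure(list(article_id = attr(stream, "article_id"), W = as.numeric(W),
                 K = tab(kc), M = tab(mc)),
            class = "article_cluster_counts")
}

empty_correlation_matrix <- function(rows, cols) {
  structure(matrix(0, length(rows), length(cols),
                   dimnames = list(rows, cols)),
            class = c("correlation_matrix", "matrix", "array"))
}

#' Per-article correlation contribution
#'
#' If the article has both keyword and method tokens, returns the matrix
#' `C_ij = W K_i M_j / sum(K_i M_j)` (so its total is exactly `W`); otherwise
#' a zero matrix.
#'
#' @param counts An `article_cluster_counts`.
#' @param rows,cols Full sets of keyword / method cluster names fixing the
#'   matrix dimensions.
#' @return A `correlation_matrix`.
#' @export
article_correlation <- function(counts, rows, cols) {
  out <- empty_correlation_matrix(rows, cols)
  if (length(counts$K) == 0L || length(counts$M) == 0L) return(out)
  block <- outer(as.numeric(counts$K), as.numeric(counts$M))
  out[names(counts$K), names(counts$M)] <- counts$W * block / sum(block)
  out
}

#' Aggregate correlation contributions
#'
#' Elementwise sum over articles; the grand total equals the summed citation
#' weights of articles having both keyword and method tokens.
#'
#' @param contributions List of `correlation_matrix` objects with identical
#'   dimensions and dimnames.
#' @return A `correlation_matrix`.
#' @export
aggregate_correlation <- function(contributions) {
  if (length(contributions) == 0L) return(empty_correlation_matrix(character(), character()))
  dn <- dimnames(contributions[[1]])
  for (m in contributions)
    if (!identical(dim(m), dim(contributions[[1]])) ||
        !identical(dimnames(m), dn))
      stop_semkos("contribution matrices must share dimensions and dimnames")
  out <- Reduce(`+`, lapply(contributions, unclass))
  structure(out, class = c("correlation_matrix", "matrix", "array"))
}

#' Correlation matrix over a tokenized corpus
#'
#' Convenience wrapper: counts, per-article contributions and aggregation in
#' one call.
#'
#' @param streams Named list of `token_stream` objects.
#' @param kwd_kos,mtd_kos `kos` objects.
#' @param citations Named numeric vector `article_id -> citations` (missing
#'   articles weigh 0).
#' @return A `correlation_matrix`.
#' @export
correlation_matrix <- function(streams, kwd_kos, mtd_kos, citations) {
  rows <- kos_level2_names(kwd_kos)
  cols <- kos_level2_names(mtd_kos)
  kmap <- kos_term_map(kwd_kos)
  mmap <- kos_term_map(mtd_kos)
  out <- empty_correlation_matrix(rows, cols)
  for (s in streams) {
    id <- attr(s, "article_id")
    W <- citations[[id]] %||% 0
    if (is.na(W)) W <- 0
    kc <- kmap[s$term_id]; kc <- kc[!is.na(kc)]
    mc <- mmap[s$term_id]; mc <- mc[!is.na(mc)]
    if (length(kc) == 0L || length(mc) == 0L) next
    K <- table(kc); M <- table(mc)
    block <- outer(as.numeric(K), as.numeric(M))
    out[names(K), names(M)] <- out[names(K), names(M)] +
      as.numeric(W) * block / sum(block)
  }
  out
}

#' Log heat-map matrix
#'
#' Natural log of the positive entries; zero entries are masked (`NA`), never
#' emitted as `-Inf`.
#'
#' @param matrix A `correlation_matrix` (or plain matrix).
#' @return Numeric matrix with `NA` for masked cells.
#' @export
log_heatmap_matrix <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  out <- ifelse(m > 0, log(m), NA_real_)
  dimnames(out) <- dimnames(m)
  out
}

#' Top-k keyword-method cluster combinations
#'
#' @param matrix A `correlation_matrix`.
#' @param k Number of combinations (if `k` exceeds the cell count, all cells
#'   are returned).
#' @return Data frame `keyword`, `method`, `value`, in descending value order;
#'   ties broken by (row, col) index.
#' @export
rank_top_combinations <- function(matrix, k) {
  stopifnot(k >= 1L)
  m <- unclass(as.matrix(matrix))
  idx <- which(!is.na(m))
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  o <- order(-m[idx], rows, cols)
  o <- o[seq_len(min(k, length(o)))]
  data.frame(keyword = rownames(m)[rows[o]] %||% as.character(rows[o]),
             method = colnames(m)[cols[o]] %||% as.character(cols[o]),
             value = m[idx[o]], stringsAsFactors = FALSE, row.names = NULL)
}

#' Bin correlation values for the power-law diagnostic
#'
#' Values are assigned to half-open bins `[lo, lo+10)` for `lo = 10, 20, ...,
#' 380`, with a closed top bin `[390, 400]`; values below 10 or above 400 are
#' discarded.
#'
#' @param x A `correlation_matrix`, matrix, or numeric vector of values.
#' @return A `power_law_bins` data frame with columns `lo`, `hi`, `count`
#'   (39 bins).
#' @export
bin_correlation_counts <- function(x) {
  v <- as.numeric(unclass(as.matrix(x)))
  v <- v[!is.na(v)]
  lo <- seq(10, 390, by = 10)
  hi <- lo + 10
  count <- vapply(seq_along(lo), function(i) {
    if (i < length(lo)) sum(v >= lo[i] & v < hi[i])
    else sum(v >= lo[i] & v <= hi[i])  # top bin closed at 400
  }, integer(1))
  structure(data.frame(lo = lo, hi = hi, count = count),
            class = c("power_law_bins", "data.frame"))
}

#' Fit a power law to binned counts
#'
#' Least squares on (log bin center, log count) over the positive-count bins,
#' with each bin weighted by its count. The weighting matters: tail bins hold
#' 0 or 1 observations, and under unweighted least squares their `log 1 = 0`
#' values flatten the slope and bias the exponent low; count weights (the
#' usual Poisson-variance weighting for binned log-log fits) concentrate the
#' fit where the bin counts actually estimate the density. The exponent is
#' the magnitude of the slope.
#'
#' @param bins A `power_law_bins` data frame (`lo`, `hi`, `count`).
#' @return List with `exponent`, `intercept`, `r_squared`.
#' @export
fit_power_law <- function(bins) {
  pos <- bins$count > 0
  if (sum(pos) < 3L)
    stop_semkos("need at least 3 bins with positive counts to fit")
  x <- log((bins$lo[pos] + bins$hi[pos]) / 2)
  y <- log(bins$count[pos])
  fit <- stats::lm(y ~ x, weights = bins$count[pos])
  list(exponent = abs(unname(stats::coef(fit)[2])),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Write a correlation matrix (or its masked log) as TSV
#'
#' Row names are keyword clusters, column names method clusters; masked cells
#' are written empty.
#'
#' @param matrix A matrix.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  m <- unclass(as.matrix(matrix))
  df <- data.frame(cluster = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Plot the log heat map of a correlation matrix
#'
#' Keyword clusters on rows, method clusters on columns; masked (zero) cells
#' in the background colour.
#'
#' @param matrix A `correlation_matrix`.
#' @param path Output image path (`.png`).
#' @return `path` invisibly.
#' @export
plot_heatmap <- function(matrix, path) {
  lm_ <- log_heatmap_matrix(matrix)
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(t(lm_[rev(seq_len(nrow(lm_))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, xlab = "method clusters",
                  ylab = "keyword clusters")
  invisible(path)
}
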