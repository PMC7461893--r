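counts_of <- function(W, K, M, id = "A") {
  structure(list(article_id = id, W = W, K = K, M = M),
            class = "article_cluster_counts")
}

test_that("a single keyword-method pair receives the full article weight", {
  for (a in c(1, 3)) for (b in c(1, 5)) {
    m <- article_correlation(counts_of(7, c(A = a), c(B = b)), "A", "B")
    expect_equal(m["A", "B"], 7)
  }
})

test_that("the worked two-keyword example distributes weight by count products", {
  m <- article_correlation(counts_of(9, c(A = 2, B = 1), c(C = 3)),
                           c("A", "B"), "C")
  expect_equal(m["A", "C"], 6)
  expect_equal(m["B", "C"], 3)
})

test_that("articles lacking either token kind contribute a zero matrix", {
  z1 <- article_correlation(counts_of(9, c(A = 2), setNames(integer(0),
                                                            character(0))),
                            "A", "B")
  z2 <- article_correlation(counts_of(9, setNames(integer(0), character(0)),
                                      c(B = 2)), "A", "B")
  expect_true(all(z1 == 0) && all(z2 == 0))
})

test_that("per-article mass is conserved over random count configurations", {
  withr::local_seed(21)
  rows <- paste0("K", 1:6); cols <- paste0("M", 1:5)
  for (i in 1:200) {
    nk <- sample(1:6, 1); nm <- sample(1:5, 1)
    K <- setNames(sample(1:9, nk, replace = TRUE), sample(rows, nk))
    M <- setNames(sample(1:9, nm, replace = TRUE), sample(cols, nm))
    W <- sample(0:1000, 1)
    m <- article_correlation(counts_of(W, K, M), rows, cols)
    expect_lt(abs(sum(m) - W), 1e-9 * max(W, 1))
  }
})

test_that("aggregation is an elementwise sum, linear and scale-equivariant", {
  rows <- c("A", "B"); cols <- c("C", "D")
  c1 <- article_correlation(counts_of(4, c(A = 1), c(C = 2)), rows, cols)
  c2 <- article_correlation(counts_of(6, c(B = 2), c(D = 1)), rows, cols)
  agg <- aggregate_correlation(list(c1, c2))
  expect_equal(unclass(agg), unclass(c1) + unclass(c2))
  expect_equal(sum(agg), 10)
  # linearity over a split of the article list
  c3 <- article_correlation(counts_of(5, c(A = 2, B = 1), c(C = 1)), rows, cols)
  whole <- aggregate_correlation(list(c1, c2, c3))
  parts <- aggregate_correlation(list(aggregate_correlation(list(c1, c2)), c3))
  expect_equal(unclass(whole), unclass(parts))
  # doubling every W doubles every cell
  d1 <- article_correlation(counts_of(8, c(A = 1), c(C = 2)), rows, cols)
  d2 <- article_correlation(counts_of(12, c(B = 2), c(D = 1)), rows, cols)
  expect_equal(unclass(aggregate_correlation(list(d1, d2))),
               2 * unclass(aggregate_correlation(list(c1, c2))))
  expect_error(aggregate_correlation(list(c1, article_correlation(
    counts_of(1, c(A = 1), c(C = 1)), rows, "C"))), "dimensions")
})

test_that("cluster counts map tokens through both KOS and ignore the rest", {
  kl <- make_lexicon(keywords = c("alpha", "beta", "orphan"),
                     methods = c("gamma"))
  stream <- recognize_terms("alpha beta alpha gamma orphan.", kl)
  attr(stream, "article_id") <- "A"
  kv <- unit_vectors(c("kwd1", "kwd2"), dim = 3)
  mv <- unit_vectors(c("mtd1"), dim = 3, center = matrix(c(0, 0, 1), 1))
  kwd_tree <- agglomerate_average_linkage(pairwise_distances(vector_table_of(kv)))
  kwd_kos <- annotate_cluster(kos_new(kwd_tree), 3L, "letters")
  # single-leaf method tree is impossible (n >= 2), so pad with a second term
  mv2 <- unit_vectors(c("mtd1", "mtd9"), dim = 3,
                      center = rbind(c(0, 0, 1), c(0, 1, 0)))
  mtd_tree <- agglomerate_average_linkage(pairwise_distances(vector_table_of(mv2)))
  mtd_kos <- annotate_cluster(kos_new(mtd_tree), 1L, "greek")
  cc <- article_cluster_counts(stream, kwd_kos, mtd_kos, W = 5)
  expect_identical(cc$K, c(letters = 3L))  # alpha x2 + beta x1; orphan ignored
  expect_identical(cc$M, c(greek = 1L))
  expect_identical(cc$W, 5)
})

test_that("log heat map masks zeros and is monotone on positive cells", {
  m <- matrix(c(exp(1), 0, 2, 8), 2, 2)
  lm_ <- log_heatmap_matrix(m)
  expect_equal(lm_[1, 1], 1)
  expect_true(is.na(lm_[2, 1]))
  expect_true(lm_[2, 2] > lm_[1, 2])
})

test_that("top combinations rank by value with (row, col) tie-breaks", {
  m <- matrix(c(5, 2, 2, 1), 2, 2,
              dimnames = list(c("K1", "K2"), c("M1", "M2")))
  top <- rank_top_combinations(m, 3)
  expect_identical(top$keyword, c("K1", "K1", "K2"))  # row breaks the 2-2 tie
  expect_identical(top$method, c("M1", "M2", "M1"))
  expect_identical(rank_top_combinations(m, 1)$value, 5)
  expect_identical(nrow(rank_top_combinations(m, 99)), 4L)
})

test_that("binning covers [10, 400] in 39 bins and discards outside values", {
  b <- bin_correlation_counts(c(15, 25, 25))
  expect_identical(nrow(b), 39L)
  expect_identical(b$count[b$lo == 10], 1L)
  expect_identical(b$count[b$lo == 20], 2L)
  expect_identical(sum(b$count), 3L)
  expect_identical(sum(bin_correlation_counts(c(5, 405, 9.999))$count), 0L)
  expect_identical(bin_correlation_counts(400)$count[39], 1L)  # top bin closed
  expect_identical(bin_correlation_counts(10)$count[1], 1L)
  vals <- c(runif(50, 0, 500))
  expect_identical(sum(bin_correlation_counts(vals)$count),
                   sum(vals >= 10 & vals <= 400))
})

test_that("exact power-law bins recover the exponent to numerical precision", {
  lo <- seq(10, 390, 10)
  centers <- (lo + lo + 10) / 2
  bins <- structure(data.frame(lo = lo, hi = lo + 10,
                               count = 1e6 * centers^(-2)),
                    class = c("power_law_bins", "data.frame"))
  fit <- fit_power_law(bins)
  expect_equal(fit$exponent, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("zero-count bins are excluded; too few positive bins error", {
  lo <- seq(10, 390, 10)
  count <- rep(0, 39); count[c(1, 5, 9)] <- c(100, 4, 1)
  bins <- structure(data.frame(lo = lo, hi = lo + 10, count = count),
                    class = c("power_law_bins", "data.frame"))
  expect_silent(fit_power_law(bins))
  count2 <- rep(0, 39); count2[c(1, 2)] <- 5
  bins2 <- structure(data.frame(lo = lo, hi = lo + 10, count = count2),
                     class = c("power_law_bins", "data.frame"))
  expect_error(fit_power_law(bins2), "at least 3")
})
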