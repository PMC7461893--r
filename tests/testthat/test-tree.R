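test_that("two leaves merge into node 3 at their distance", {
  d <- matrix(c(0, 2.5, 2.5, 0), 2, 2, dimnames = list(c("kwd1", "kwd2"),
                                                       c("kwd1", "kwd2")))
  tr <- agglomerate_average_linkage(d)
  expect_identical(tr$merges$a, 1L)
  expect_identical(tr$merges$b, 2L)
  expect_equal(tr$merges$height, 2.5)
  expect_identical(tr$leaf_labels, c("kwd1", "kwd2"))
  expect_error(agglomerate_average_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("hand-worked four-leaf case merges pairs then the pair of pairs", {
  d <- matrix(10, 4, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 2
  diag(d) <- 0
  tr <- agglomerate_average_linkage(d)
  expect_equal(tr$merges,
               data.frame(a = c(1L, 3L, 5L), b = c(2L, 4L, 6L),
                          height = c(1, 2, 10)))
})

test_that("exact ties merge the pair with the smallest label key", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  tr <- agglomerate_average_linkage(d)
  expect_identical(tr$merges$a, c(1L, 3L, 5L))
  expect_identical(tr$merges$b, c(2L, 4L, 6L))
})

test_that("merge order and heights match the naive all-pairs oracle", {
  withr::local_seed(99)
  for (i in 1:30) {
    n <- sample(2:30, 1)
    d <- random_dist_matrix(n)
    tr <- agglomerate_average_linkage(d)
    oracle <- oracle_upgma(d)
    expect_identical(tr$merges$a, oracle$a)
    expect_identical(tr$merges$b, oracle$b)
    expect_equal(tr$merges$height, oracle$height, tolerance = 1e-9)
  }
})

test_that("partitions agree with hclust average linkage on tie-free input", {
  withr::local_seed(3)
  d <- random_dist_matrix(20)
  tr <- agglomerate_average_linkage(d)
  h <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(tr$merges$height, h$height, tolerance = 1e-9)
  for (k in c(2, 5, 9)) {
    a <- cut_tree(tr, k)
    b <- stats::cutree(h, k)
    expect_equal(mclust::adjustedRandIndex(a, b), 1)
  }
})

test_that("built trees satisfy the labelling and height invariants", {
  withr::local_seed(17)
  for (i in 1:10) {
    n <- sample(2:40, 1)
    tr <- agglomerate_average_linkage(random_dist_matrix(n))
    expect_true(validate_merge_tree(tr))
    expect_length(branch_terms(tr, 2L * n - 1L), n)
    if (n >= 3) {
      node <- sample((n + 1L):(2L * n - 1L), 1)
      kids <- c(tr$merges$a[node - n], tr$merges$b[node - n])
      expect_setequal(branch_terms(tr, node),
                      c(branch_terms(tr, kids[1]), branch_terms(tr, kids[2])))
    }
  }
})

test_that("branch_terms handles leaves, root and invalid labels", {
  tr <- agglomerate_average_linkage(random_dist_matrix(5))
  expect_identical(branch_terms(tr, 2L), tr$leaf_labels[2])
  expect_setequal(branch_terms(tr, 9L), tr$leaf_labels)
  expect_error(branch_terms(tr, 10L), "invalid node")
  expect_error(branch_terms(tr, 0L), "invalid node")
})

test_that("branch review sampling honours the budget and is deterministic", {
  d <- matrix(10, 4, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("kwd", 1:4)
  tr <- agglomerate_average_linkage(d)
  expect_setequal(sample_branch_for_review(tr, 7L, budget = 10L),
                  paste0("kwd", 1:4))
  # budget 2 at the root: one representative from each child subtree
  picks <- sample_branch_for_review(tr, 7L, budget = 2L, seed = 4L)
  expect_length(picks, 2L)
  expect_length(intersect(picks, c("kwd1", "kwd2")), 1L)
  expect_length(intersect(picks, c("kwd3", "kwd4")), 1L)
  expect_identical(picks, sample_branch_for_review(tr, 7L, budget = 2L,
                                                   seed = 4L))
})

test_that("tree exports: newick parses, json round-trips, indented text has 2n-1 lines", {
  withr::local_seed(12)
  n <- 7L
  d <- random_dist_matrix(n)
  rownames(d) <- colnames(d) <- paste0("kwd", seq_len(n))
  tr <- agglomerate_average_linkage(d)
  phy <- ape::read.tree(text = export_tree(tr, "newick"))
  expect_identical(ape::Ntip(phy), n)
  expect_setequal(phy$tip.label, paste0("kwd", seq_len(n)))
  expect_true(all(phy$edge.length >= -1e-12))
  expect_equal(import_tree_json(export_tree(tr, "json")), tr)
  expect_length(strsplit(export_tree(tr, "indented-text"), "\n")[[1]],
                2L * n - 1L)
  expect_error(export_tree(tr, "yaml"), "unknown")
})

test_that("cophenetic root height is preserved in the newick export", {
  d <- matrix(10, 4, 4)
  d[1, 2] <- d[2, 1] <- 2
  d[3, 4] <- d[4, 3] <- 4
  diag(d) <- 0
  tr <- agglomerate_average_linkage(d)
  phy <- ape::read.tree(text = export_tree(tr, "newick"))
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths), 10, tolerance = 1e-9)
})
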