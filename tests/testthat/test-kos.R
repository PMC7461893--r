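prosocial_fixture <- function() {
  terms <- c("altruism", "prosocial behavior", "prosociality", "prosocial",
             "fairness", "unfairness", "social norm", "social distance")
  v <- unit_vectors(terms, dim = 4,
                    center = diag(4)[rep(1:4, each = 2), ], noise = 0.1)
  tab <- vector_table_of(v)
  tree <- agglomerate_average_linkage(pairwise_distances(tab))
  list(tree = tree, tab = tab, terms = terms)
}

test_that("a monophyletic branch can be named, and members are its leaves", {
  fx <- prosocial_fixture()
  ks <- kos_new(fx$tree)
  node <- 2L * fx$tree$n_leaves - 1L  # root covers every term
  ks <- annotate_cluster(ks, node, "prosociality")
  expect_setequal(kos_members(ks, "prosociality"), fx$terms)
  expect_identical(kos_level2_names(ks), "prosociality")
})

test_that("paraphyletic unions: two sibling branches may share one name", {
  fx <- prosocial_fixture()
  root <- 2L * fx$tree$n_leaves - 1L
  kids <- c(fx$tree$merges$a[root - fx$tree$n_leaves],
            fx$tree$merges$b[root - fx$tree$n_leaves])
  ks <- annotate_cluster(kos_new(fx$tree), kids, "social research")
  expect_setequal(kos_members(ks, "social research"), fx$terms)
  expect_length(ks$annotations, 1L)
})

test_that("level-2 annotations must be disjoint on terms", {
  fx <- prosocial_fixture()
  root <- 2L * fx$tree$n_leaves - 1L
  ks <- annotate_cluster(kos_new(fx$tree), 1L, "one")
  err <- tryCatch(annotate_cluster(ks, root, "two"), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), fx$tree$leaf_labels[1], fixed = TRUE)
  expect_error(annotate_cluster(ks, 99L, "bad"), "invalid node")
})

test_that("annotation events append to the review log", {
  fx <- prosocial_fixture()
  ks <- annotate_cluster(kos_new(fx$tree), 1L, "one")
  ks <- annotate_cluster(ks, 2L, "two")
  expect_length(ks$log, 2L)
  expect_identical(ks$log[[2]]$action, "annotate")
})

test_that("cluster representation is the plain mean of member unit vectors", {
  v <- matrix(c(1, 0, -1, 0, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), NULL))
  tab <- vector_table_of(v)
  d <- pairwise_distances(tab)
  tree <- agglomerate_average_linkage(d)
  ks <- annotate_cluster(kos_new(tree), 3L, "single")
  single <- cluster_representation(ks, "single", tab)
  expect_equal(single, v[branch_terms(tree, 3L), ], ignore_attr = TRUE)
  # opposite unit vectors average to zero; permutation invariant
  ks2 <- annotate_cluster(kos_new(tree), which(tree$leaf_labels == "t1"), "pair")
  ks2 <- annotate_cluster(ks2, which(tree$leaf_labels == "t2"), "pair")
  expect_equal(cluster_representation(ks2, "pair", tab), c(0, 0),
               ignore_attr = TRUE)
})

test_that("level-3 regrouping recovers two planted super-groups", {
  withr::local_seed(8)
  terms <- paste0("t", 1:12)
  centers <- rbind(matrix(rep(c(1, 0, 0, 0), 6), 6, byrow = TRUE),
                   matrix(rep(c(0, 0, 1, 0), 6), 6, byrow = TRUE))
  v <- unit_vectors(terms, dim = 4, center = centers, noise = 0.08)
  tab <- vector_table_of(v)
  tree <- agglomerate_average_linkage(pairwise_distances(tab))
  ks <- kos_from_cut(tree, 6)
  expect_error(regroup_level3(kos_new(tree), tab), "at least 2")
  ks <- regroup_level3(ks, tab, k = 2L)
  l2 <- kos_level2_names(ks)
  expect_identical(sort(unique(unname(ks$level3_parent))),
                   c("level3_1", "level3_2"))
  expect_true(all(l2 %in% names(ks$level3_parent)))
  # super-group membership follows the planted halves
  planted <- vapply(l2, function(nm)
    mean(match(kos_members(ks, nm), terms) <= 6) > 0.5, logical(1))
  expect_identical(length(unique(ks$level3_parent[planted])), 1L)
  expect_identical(length(unique(ks$level3_parent[!planted])), 1L)
  expect_false(unique(ks$level3_parent[planted]) ==
                 unique(ks$level3_parent[!planted]))
})

test_that("landscape layout scales dot areas with citations and keys level 3", {
  fx <- prosocial_fixture()
  ks <- kos_from_cut(fx$tree, 4)
  ks <- regroup_level3(ks, fx$tab, k = 2L)
  nm <- kos_level2_names(ks)
  cit <- setNames(c(100, 400, 250, 50), nm)
  lay <- layout_landscape(ks, fx$tab, cit)
  expect_identical(nrow(lay), 4L)
  expect_equal(lay$area[lay$name == nm[2]] / lay$area[lay$name == nm[1]], 4)
  expect_identical(length(unique(lay$level3)),
                   length(unique(unname(ks$level3_parent))))
  expect_true(all(is.finite(lay$x) & is.finite(lay$y)))
  expect_warning(layout_landscape(ks, fx$tab, cit[-1]), "missing citation")
})

test_that("a cut-based KOS template has k disjoint monophyletic clusters", {
  fx <- prosocial_fixture()
  ks <- kos_from_cut(fx$tree, 3)
  expect_length(ks$annotations, 3L)
  members <- unlist(lapply(kos_level2_names(ks), kos_members, kos = ks))
  expect_setequal(members, fx$terms)
  expect_identical(anyDuplicated(members), 0L)
})

test_that("KOS annotations round-trip through TSV", {
  fx <- prosocial_fixture()
  ks <- regroup_level3(kos_from_cut(fx$tree, 4), fx$tab, k = 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kos_tsv(ks, f)
  back <- read_kos_tsv(f, fx$tree)
  expect_identical(kos_level2_names(back), kos_level2_names(ks))
  for (nm in kos_level2_names(ks))
    expect_setequal(kos_members(back, nm), kos_members(ks, nm))
  expect_identical(back$level3_parent[kos_level2_names(back)],
                   ks$level3_parent[kos_level2_names(ks)])
})
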