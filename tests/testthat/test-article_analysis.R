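# shared fixture: a small corpus with one keyword KOS of two clusters
coverage_fixture <- function() {
  lex <- make_lexicon(keywords = c("alpha", "beta", "gamma", "delta"))
  v <- unit_vectors(paste0("kwd", 1:4), dim = 4)
  tree <- agglomerate_average_linkage(pairwise_distances(vector_table_of(v)))
  ks <- kos_new(tree)
  ks <- annotate_cluster(ks, which(tree$leaf_labels == "kwd1"), "A")
  ks <- annotate_cluster(ks, which(tree$leaf_labels == "kwd2"), "B")
  # 10 articles: exactly 6 contain the cluster-A term, 3 the cluster-B term
  bodies <- c(rep("alpha seen here.", 6), rep("beta instead.", 3),
              "gamma only.")
  arts <- lapply(seq_along(bodies), function(i)
    make_article(sprintf("P%02d", i), body = bodies[i]))
  streams <- tokenize_corpus(arts, lex)
  list(lex = lex, kos = ks, streams = streams,
       ids = vapply(arts, function(a) a$article_id, character(1)))
}

test_that("retrieval selects exactly the articles containing a member term", {
  fx <- coverage_fixture()
  grp <- retrieve_articles(fx$kos, "A", fx$streams)
  expect_identical(sort(grp$members), sprintf("P%02d", 1:6))
  expect_identical(attr(grp, "cluster"), "A")
  grpB <- retrieve_articles(fx$kos, "B", fx$streams)
  expect_identical(sort(grpB$members), sprintf("P%02d", 7:9))
})

test_that("coverage matches the definitional 60% example and its edge cases", {
  fx <- coverage_fixture()
  cov <- coverage_vector(fx$ids, fx$streams, fx$kos)
  expect_equal(cov[["A"]], 0.6)
  expect_equal(cov[["B"]], 0.3)
  allA <- coverage_vector(sprintf("P%02d", 1:6), fx$streams, fx$kos)
  expect_equal(allA[["A"]], 1)
  expect_equal(allA[["B"]], 0)
})

test_that("coverage equals retrieval intersection and pools by weighted mean", {
  fx <- coverage_fixture()
  grpA <- retrieve_articles(fx$kos, "A", fx$streams)
  for (sub in list(fx$ids, fx$ids[1:4], fx$ids[5:10])) {
    cov <- coverage_vector(sub, fx$streams, fx$kos)
    expect_equal(cov[["A"]], length(intersect(grpA$members, sub)) / length(sub))
  }
  g1 <- fx$ids[1:4]; g2 <- fx$ids[5:10]
  pooled <- coverage_vector(fx$ids, fx$streams, fx$kos)
  weighted <- (4 * coverage_vector(g1, fx$streams, fx$kos) +
                 6 * coverage_vector(g2, fx$streams, fx$kos)) / 10
  expect_equal(pooled, weighted)
})

test_that("coverage differences subtract per cluster and stay in [-1, 1]", {
  fx <- coverage_fixture()
  expect_equal(coverage_difference(fx$ids, fx$ids, fx$streams, fx$kos),
               setNames(c(0, 0), c("A", "B")))
  d <- coverage_difference(fx$ids[1:5], fx$ids, fx$streams, fx$kos)
  expect_equal(d[["A"]], 1 - 0.6)
  expect_true(all(d >= -1 & d <= 1))
})

test_that("affinity propagation separates two blobs with interior exemplars", {
  withr::local_seed(31)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  rownames(X) <- paste0("p", 1:40)
  fit <- affinity_propagation(X)
  expect_true(fit$converged)
  expect_length(fit$exemplars, 2L)
  expect_setequal(unique((fit$labels[1:20])), fit$exemplars[fit$exemplars <= 20])
  expect_setequal(unique((fit$labels[21:40])), fit$exemplars[fit$exemplars > 20])
  # exemplars are fixed points of their own cluster
  expect_identical(unname(fit$labels[fit$exemplars]), fit$exemplars)
  # no internal randomness
  expect_identical(fit, affinity_propagation(X))
})

test_that("identical points collapse to a single cluster", {
  X <- matrix(1, 5, 3, dimnames = list(paste0("p", 1:5), NULL))
  fit <- affinity_propagation(X)
  expect_identical(length(unique(fit$labels)), 1L)
})

test_that("multi-round clustering has weakly decreasing counts and full coverage", {
  withr::local_seed(13)
  # 3-level hierarchy: 2 far groups x 2 mid clusters x 10 points
  centers <- rbind(c(0, 0), c(0, 4), c(12, 0), c(12, 4))
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(20, 0, 0.5), 10, 2), 2, centers[i, ], "+")))
  rownames(X) <- paste0("d", 1:40)
  rc <- multiround_cluster(X, rounds = 2)
  counts <- vapply(rc$rounds, function(r) r$n_clusters, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(sort(names(rc$assignment)), sort(rownames(X)))
  expect_length(unique(rc$assignment), counts[length(counts)])
  # the top level recovers the coarsest planted split
  top <- rc$assignment
  expect_identical(length(unique(top[1:20])), 1L)
  expect_identical(length(unique(top[21:40])), 1L)
  expect_false(unique(top[1:20]) == unique(top[21:40]))
})

test_that("group profiles rank clusters and cited articles with exclusions", {
  fx <- coverage_fixture()
  grp <- retrieve_articles(fx$kos, "A", fx$streams)
  cits <- setNames(seq_along(fx$ids) * 10, fx$ids)
  prof <- profile_article_group(grp, fx$streams, fx$kos, fx$kos, cits, k = 10)
  # the retrieval cluster is excluded by default from both rankings
  expect_false("A" %in% prof$keywords$name)
  expect_true(all(diff(prof$keywords$value) <= 0))
  expect_identical(prof$top_cited$article_id[1], "P06")
  expect_identical(prof$top_cited$citations, sort(cits[grp$members],
                                                  decreasing = TRUE),
                   ignore_attr = TRUE)
  prof2 <- profile_article_group(grp, fx$streams, fx$kos, fx$kos, cits,
                                 k = 1, exclude = character())
  expect_identical(prof2$keywords$name, "A")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof2, f)
  expect_match(readLines(f)[2], "100.00%", fixed = TRUE)
})
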