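small_spec <- function(...) {
  planted_spec(n_keyword_groups = 4L, terms_per_group = 4L,
               n_method_groups = 3L, methods_per_group = 4L,
               n_articles = 60L, seed = 9L, ...)
}

test_that("the same seed reproduces a byte-identical corpus", {
  g1 <- generate_corpus(small_spec())
  g2 <- generate_corpus(small_spec())
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  g3 <- generate_corpus(planted_spec(n_keyword_groups = 4L,
                                     terms_per_group = 4L,
                                     n_method_groups = 3L,
                                     methods_per_group = 4L,
                                     n_articles = 60L, seed = 10L))
  expect_false(identical(serialize(g1, NULL), serialize(g3, NULL)))
})

test_that("nested phrase pairs occur in bodies both embedded and alone", {
  gen <- generate_corpus(small_spec())
  bodies <- vapply(gen$articles, article_text, character(1))
  expect_true(any(grepl("visual short-term memory", bodies, fixed = TRUE)))
  alone <- grepl("(?<!visual )short-term memory", bodies, perl = TRUE)
  expect_true(any(alone))
  # and the tokenizer emits only the longer phrase at the embedded site
  lex <- build_lexicon(gen$articles)
  i <- which(grepl("visual short-term memory", bodies, fixed = TRUE))[1]
  s <- recognize_terms(bodies[i], lex)
  surfs <- lex$surface[match(s$term_id, lex$term_id)]
  spans_l <- s$start[surfs == "visual short-term memory"]
  spans_s <- s$start[surfs == "short-term memory"]
  expect_false(any((spans_s - 7) %in% spans_l))  # never inside the longer one
})

test_that("malformed nested pairs are rejected", {
  expect_error(planted_spec(nested_phrase_pairs = list(c("alpha beta",
                                                         "gamma"))),
               "nested pair")
})

test_that("generated corpora survive the JATS round trip", {
  gen <- generate_corpus(small_spec())
  dir <- withr::local_tempdir()
  write_corpus_jats(gen$articles, dir)
  back <- read_jats_articles(dir, citations = read_citation_table(
    file.path(dir, "citations.tsv")))
  expect_length(back, length(gen$articles))
  ids <- vapply(back, function(a) a$article_id, character(1))
  o <- match(vapply(gen$articles, function(a) a$article_id, character(1)), ids)
  for (k in seq_along(gen$articles)) {
    expect_identical(back[[o[k]]]$author_keywords,
                     gen$articles[[k]]$author_keywords)
    expect_identical(extract_method_subtitles(back[[o[k]]]),
                     extract_method_subtitles(gen$articles[[k]]))
    expect_identical(back[[o[k]]]$citation_count,
                     gen$articles[[k]]$citation_count)
  }
})

test_that("citation counts follow the configured power-law tail", {
  gen <- generate_corpus(planted_spec(n_articles = 5000L, seed = 3L))
  cits <- vapply(gen$articles, function(a) a$citation_count, integer(1))
  fit <- fit_power_law(bin_correlation_counts(cits))
  expect_lt(abs(fit$exponent - 2), 0.3)
})

test_that("recovery scoring: identity gives ARI 1, random labels near 0", {
  truth <- setNames(rep(1:5, each = 8), paste0("t", 1:40))
  expect_equal(score_recovery(truth, truth)$ari, 1)
  withr::local_seed(2)
  aris <- replicate(50, {
    perm <- setNames(sample(1:5, 40, replace = TRUE), names(truth))
    score_recovery(perm, truth)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)
  expect_error(score_recovery(setNames(1, "other"), truth), "universe")
})

test_that("the power-law sampler respects its support and the RNG contract", {
  draws <- semkos:::with_seed(4, sample_power_law(500, 2, xmin = 1,
                                                  xmax = 100))
  expect_true(all(draws >= 1 & draws <= 100))
  expect_identical(draws,
                   semkos:::with_seed(4, sample_power_law(500, 2, xmax = 100)))
})

test_that("cluster-to-group majority mapping finds the planted groups", {
  gen <- generate_corpus(small_spec())
  lex <- build_lexicon(gen$articles)
  streams <- tokenize_corpus(gen$articles, lex)
  tab <- normalize_vectors(train_embeddings(
    streams, embedding_config(dimension = 16L, min_count = 5L,
                              random_seed = 9L)))
  ids <- intersect(lex$term_id[lex$kind == "keyword"],
                   rownames(tab$term_vectors))
  tree <- agglomerate_average_linkage(pairwise_distances(tab, ids))
  ks <- kos_from_cut(tree, 4)
  maj <- majority_planted_group(ks, lex, gen$truth$term_group)
  expect_identical(sort(unique(unname(maj))), 1:4)
})
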