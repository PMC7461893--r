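# Planted-structure synthetic corpora. Articles emulate the statistics the
# pipeline assumes: an author-keyword section sampled from the article's topic
# group, a methods-like section whose subtitles come from a method-name
# vocabulary (with one keyword-group/method-group pair boosted to plant a
# co-occurrence affinity block), body sentences mixing group terms with
# group-specific or shared context words, nested multiword phrases, and
# heavy-tailed citation counts from a truncated discrete power law.

#' Specification of a planted synthetic corpus
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 10 keyword groups of 8 terms, 5 method groups of 6 methods, one
#' nested phrase pair, separation 0.9 (a body term or context word is drawn
#' from the article's own group with probability 0.9), a single affinity block
#' boosted 10-fold, 2,000 articles, and a citation tail exponent of 2.
#'
#' @param n_keyword_groups,terms_per_group,n_method_groups,methods_per_group
#'   Vocabulary shape (all >= 1; `terms_per_group >= 2` when nested pairs are
#'   planted).
#' @param nested_phrase_pairs List of `c(longer, shorter)` phrase pairs; the
#'   shorter phrase must be a contiguous word subsequence of the longer one.
#'   Pair i is planted into keyword group `((i-1) %% n_keyword_groups) + 1`.
#' @param context_pool_size Context words per group (and in the shared pool).
#' @param group_separation Probability in `[0, 1]` that a body term / context
#'   word is group-specific rather than drawn from another group / the shared
#'   pool.
#' @param affinity_block List `(kwd_group, mtd_group, multiplier)`; articles
#'   of the keyword group pick the method group with `multiplier`-fold odds.
#' @param n_articles Number of articles.
#' @param citation_tail_exponent Exponent of the citation power law.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A `planted_spec` list.
#' @export
planted_spec <- function(n_keyword_groups = 10L, terms_per_group = 8L,
                         n_method_groups = 5L, methods_per_group = 6L,
                         nested_phrase_pairs = list(
                           c("visual short-term memory", "short-term memory")),
                         context_pool_size = 30L, group_separation = 0.9,
                         affinity_block = list(kwd_group = 1L, mtd_group = 1L,
                                               multiplier = 10),
                         n_articles = 2000L, citation_tail_exponent = 2.0,
                         seed = 1L) {
  stopifnot(n_keyword_groups >= 1L, terms_per_group >= 1L,
            n_method_groups >= 1L, methods_per_group >= 1L,
            context_pool_size >= 1L, n_articles >= 1L,
            group_separation >= 0, group_separation <= 1,
            affinity_block$multiplier >= 1)
  for (p in nested_phrase_pairs) {
    lw <- split_words(p[1])$words
    sw <- split_words(p[2])$words
    ok <- length(sw) >= 1L && length(sw) < length(lw) &&
      any(vapply(seq_len(length(lw) - length(sw) + 1L), function(i)
        identical(lw[i:(i + length(sw) - 1L)], sw), logical(1)))
    if (!ok)
      stop_semkos("inconsistent nested pair: '", p[2],
                  "' is not a proper contiguous subsequence of '", p[1], "'")
    if (terms_per_group < 2L)
      stop_semkos("terms_per_group must be >= 2 to plant a nested pair")
  }
  structure(list(n_keyword_groups = as.integer(n_keyword_groups),
                 terms_per_group = as.integer(terms_per_group),
                 n_method_groups = as.integer(n_method_groups),
                 methods_per_group = as.integer(methods_per_group),
                 nested_phrase_pairs = nested_phrase_pairs,
                 context_pool_size = as.integer(context_pool_size),
                 group_separation = group_separation,
                 affinity_block = affinity_block,
                 n_articles = as.integer(n_articles),
                 citation_tail_exponent = citation_tail_exponent,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Sample a truncated discrete power law by inverse CDF
#'
#' `P(k)` proportional to `k^-exponent` on the integer support
#' `[xmin, xmax]`.
#'
#' @param n Number of draws.
#' @param exponent Tail exponent (> 1 for a heavy tail).
#' @param xmin,xmax Integer support bounds.
#' @return Integer vector.
#' @export
sample_power_law <- function(n, exponent, xmin = 1L, xmax = 10000L) {
  support <- seq.int(xmin, xmax)
  p <- support^(-exponent)
  cdf <- cumsum(p) / sum(p)
  support[findInterval(runif(n), cdf) + 1L]
}

FILLER_WORDS <- c("the", "of", "a", "in", "and", "to", "for", "with", "was",
                  "were", "is", "that", "this", "on", "by", "from", "at",
                  "as", "an", "observed")

planted_vocabulary <- function(spec) {
  kw <- lapply(seq_len(spec$n_keyword_groups), function(g)
    vapply(seq_len(spec$terms_per_group), function(t)
      if (t %% 2L == 1L) sprintf("kw%02dgene%02d", g, t)
      else sprintf("kw%02d pathway%02d", g, t), character(1)))
  for (i in seq_along(spec$nested_phrase_pairs)) {
    g <- ((i - 1L) %% spec$n_keyword_groups) + 1L
    p <- spec$nested_phrase_pairs[[i]]
    kw[[g]][spec$terms_per_group - 1L] <- normalize_surface(p[1])
    kw[[g]][spec$terms_per_group] <- normalize_surface(p[2])
  }
  mt <- lapply(seq_len(spec$n_method_groups), function(h)
    vapply(seq_len(spec$methods_per_group), function(m)
      if (m %% 2L == 1L) sprintf("proc%02dassay%02d", h, m)
      else sprintf("proc%02d protocol%02d", h, m), character(1)))
  ctx <- lapply(seq_len(spec$n_keyword_groups), function(g)
    sprintf("ctx%02dword%02d", g, seq_len(spec$context_pool_size)))
  shared <- sprintf("commonword%02d", seq_len(spec$context_pool_size))
  list(keywords = kw, methods = mt, context = ctx, shared = shared)
}

#' Generate a synthetic corpus with ground truth
#'
#' See [planted_spec()] for the generating model. The same seed yields a
#' byte-identical corpus; the caller's RNG state is untouched.
#'
#' @param spec A `planted_spec`.
#' @return List with `articles` (list of `article_record`) and `truth`, a
#'   `ground_truth` list: `term_group` (keyword surface -> group),
#'   `method_group` (method surface -> group; 0 is the shared pool),
#'   `article_topic` (article id -> group), `affinity_pair`.
#' @export
generate_corpus <- function(spec) {
  vocab <- planted_vocabulary(spec)
  G <- spec$n_keyword_groups
  H <- spec$n_method_groups
  sep <- spec$group_separation
  methods_titles <- c("Methods", "Materials and Methods",
                      "Experimental procedures", "Methodology")
  km <- do.call(rbind, vocab$keywords)    # G x terms_per_group surfaces
  cm <- do.call(rbind, vocab$context)     # G x context_pool_size
  pair_groups <- if (length(spec$nested_phrase_pairs))
    ((seq_along(spec$nested_phrase_pairs) - 1L) %% G) + 1L else integer(0)
  with_seed(spec$seed, {
    topics <- sample.int(G, spec$n_articles, replace = TRUE)
    citations <- sample_power_law(spec$n_articles,
                                  spec$citation_tail_exponent,
                                  xmin = 1L, xmax = 10001L) - 1L
    articles <- vector("list", spec$n_articles)
    for (i in seq_len(spec$n_articles)) {
      g <- topics[i]
      kws <- sample(vocab$keywords[[g]], sample(3:6, 1L), replace = TRUE)
      w <- rep(1, H)
      if (g == spec$affinity_block$kwd_group)
        w[spec$affinity_block$mtd_group] <- spec$affinity_block$multiplier
      h <- sample.int(H, 1L, prob = w)
      subtitles <- sample(vocab$methods[[h]],
                          min(sample(2:4, 1L), spec$methods_per_group))
      if (runif(1) < 0.6) subtitles <- c("Statistical analysis", subtitles)
      methods_body <- paste0(subtitles, " was performed as previously described.",
                             collapse = " ")
      n_sent <- sample(8:12, 1L)
      # vectorized sentence construction: draw all units for the article's
      # body at once, then regroup by sentence
      pick_groups <- function(m) {
        own <- runif(m) < sep | G == 1L
        gs <- rep.int(g, m)
        k <- sum(!own)
        if (k) gs[!own] <- ((g - 1L + sample.int(G - 1L, k, replace = TRUE))
                            %% G) + 1L
        gs
      }
      nt <- sample(1:3, n_sent, replace = TRUE)
      nc <- sample(3:6, n_sent, replace = TRUE)
      nf <- sample(3:6, n_sent, replace = TRUE)
      tg <- pick_groups(sum(nt))
      terms <- km[cbind(tg, sample.int(ncol(km), sum(nt), replace = TRUE))]
      cg <- pick_groups(sum(nc))
      own_pool <- runif(sum(nc)) < sep
      ctx <- ifelse(own_pool,
                    cm[cbind(cg, sample.int(ncol(cm), sum(nc), replace = TRUE))],
                    vocab$shared[sample.int(length(vocab$shared), sum(nc),
                                            replace = TRUE)])
      fill <- FILLER_WORDS[sample.int(length(FILLER_WORDS), sum(nf),
                                      replace = TRUE)]
      units <- c(terms, ctx, fill)
      sent_of <- c(rep.int(seq_len(n_sent), nt), rep.int(seq_len(n_sent), nc),
                   rep.int(seq_len(n_sent), nf))
      o <- order(sent_of, runif(length(units)))  # shuffle within sentence
      sentences <- vapply(split(units[o], sent_of[o]), function(u)
        paste0(paste(u, collapse = " "), "."), character(1), USE.NAMES = FALSE)
      # guarantee nested phrases occur both embedded and alone in bodies
      for (pi in which(pair_groups == g)) {
        p <- spec$nested_phrase_pairs[[pi]]
        sentences <- c(sentences,
                       paste0("the ", normalize_surface(p[1]),
                              " effect was robust."),
                       paste0("deficits in ", normalize_surface(p[2]),
                              " were reported."))
      }
      articles[[i]] <- article_record(
        article_id = sprintf("SYN%05d", i),
        title = paste("a study of", kws[1]),
        sections = list(
          section_record(title = sample(methods_titles, 1L),
                         subtitles = subtitles, body = methods_body),
          section_record(title = "Results",
                         body = paste(sentences, collapse = " "))),
        author_keywords = kws,
        citation_count = citations[i])
    }
    truth <- structure(list(
      term_group = setNames(rep(seq_len(G), each = spec$terms_per_group),
                            unlist(vocab$keywords)),
      method_group = c(setNames(rep(seq_len(H), each = spec$methods_per_group),
                                unlist(vocab$methods)),
                       setNames(0L, "statistical analysis")),
      article_topic = setNames(topics, vapply(articles, function(a)
        a$article_id, character(1))),
      affinity_pair = c(kwd_group = spec$affinity_block$kwd_group,
                        mtd_group = spec$affinity_block$mtd_group)),
      class = "ground_truth")
    list(articles = articles, truth = truth)
  })
}

#' Write a synthetic corpus as JATS-like NXML files
#'
#' Emits one `.nxml` file per article (parsable by [read_jats_articles()]),
#' plus `citations.tsv`.
#'
#' @param articles List of `article_record` objects.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_corpus_jats <- function(articles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in articles) {
    doc <- xml2::xml_new_root("article")
    front <- xml2::xml_add_child(doc, "front")
    meta <- xml2::xml_add_child(front, "article-meta")
    id <- xml2::xml_add_child(meta, "article-id", a$article_id)
    xml2::xml_set_attr(id, "pub-id-type", "pmc")
    tg <- xml2::xml_add_child(meta, "title-group")
    xml2::xml_add_child(tg, "article-title", a$title)
    if (length(a$author_keywords)) {
      kg <- xml2::xml_add_child(meta, "kwd-group")
      for (k in a$author_keywords) xml2::xml_add_child(kg, "kwd", k)
    }
    body <- xml2::xml_add_child(doc, "body")
    for (s in a$sections) {
      sec <- xml2::xml_add_child(body, "sec")
      xml2::xml_add_child(sec, "title", s$title)
      for (st in s$subtitles) {
        sub <- xml2::xml_add_child(sec, "sec")
        xml2::xml_add_child(sub, "title", st)
        xml2::xml_add_child(sub, "p", "")
      }
      if (nzchar(s$body)) xml2::xml_add_child(sec, "p", s$body)
    }
    xml2::write_xml(doc, file.path(dir, paste0(a$article_id, ".nxml")))
  }
  write_citation_tsv(articles, file.path(dir, "citations.tsv"))
  invisible(dir)
}

#' Write the citation side table for a corpus
#'
#' @param articles List of `article_record` objects.
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
write_citation_tsv <- function(articles, path) {
  df <- data.frame(
    article_id = vapply(articles, function(a) a$article_id, character(1)),
    citations = vapply(articles, function(a) a$citation_count, integer(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Score a predicted partition against the planted one
#'
#' @param predicted Named vector (names = items, values = predicted cluster
#'   ids).
#' @param truth Named vector over the same items (e.g. `truth$term_group`
#'   restricted to the clustered terms).
#' @return List with `ari`, the adjusted Rand index.
#' @export
score_recovery <- function(predicted, truth) {
  if (!setequal(names(predicted), names(truth)))
    stop_semkos("predicted and truth partitions cover different universes")
  truth <- truth[names(predicted)]
  list(ari = mclust::adjustedRandIndex(unname(predicted), unname(truth)))
}

#' Majority planted group of each level-2 cluster
#'
#' Maps every level-2 annotation to the planted group that the majority of its
#' member terms belong to (ties broken by the smaller group id). Used to
#' locate the planted affinity pair in an aggregated correlation matrix.
#'
#' @param kos A `kos`.
#' @param lexicon The `term_lexicon` (to map term ids to surfaces).
#' @param group Named vector, surface -> planted group.
#' @return Named vector, level-2 cluster name -> group id.
#' @export
majority_planted_group <- function(kos, lexicon, group) {
  surf <- setNames(lexicon$surface, lexicon$term_id)
  vapply(kos_level2_names(kos), function(nm) {
    g <- group[surf[kos_members(kos, nm)]]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_integer_)
    tab <- table(g)
    as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  }, integer(1))
}
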