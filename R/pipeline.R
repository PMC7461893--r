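# Pipeline orchestration: extract -> lexicon -> tokenize -> embed -> cluster
# -> KOS template -> correlate -> power law -> article profiling, driven by a
# single JSON configuration, with content-hash stage caching so the manual
# annotation loop can cheaply re-run everything downstream of the tree.
# Outputs carry no timestamps, so identical config + seed reproduce identical
# artifact hashes.

PIPELINE_STAGES <- c("corpus", "lexicon", "tokenize", "embed", "cluster",
                     "kos", "correlate", "powerlaw", "articles")

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param input Either a path to JATS files, or `NULL` to generate a synthetic
#'   corpus from `synthetic`.
#' @param citations Optional citation TSV path (ignored for synthetic runs,
#'   which carry their own).
#' @param synthetic A [planted_spec()]-style list used when `input` is `NULL`.
#' @param seed Master seed, recorded in the manifest.
#' @param stages Stages to run, in order (subset of
#'   `corpus, lexicon, tokenize, embed, cluster, kos, correlate, powerlaw,
#'   articles`).
#' @param embedding Overrides for [embedding_config()].
#' @param n_keyword_clusters,n_method_clusters Cut sizes for the KOS template.
#' @param level3_k Level-3 group count (`NULL` = default granularity).
#' @param filter Thresholds for [filter_lexicon()].
#' @param profile_cluster Level-2 keyword cluster to retrieve and profile
#'   (`"auto"` = the largest cluster).
#' @param ap_rounds Multi-round affinity propagation rounds.
#' @param top_k Entries in the top-combinations and profile reports.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, input = NULL, citations = NULL,
                       synthetic = list(), seed = 1L,
                       stages = PIPELINE_STAGES, embedding = list(),
                       n_keyword_clusters = 10L, n_method_clusters = 5L,
                       level3_k = NULL, filter = list(),
                       profile_cluster = "auto", ap_rounds = 2L,
                       top_k = 20L) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop_semkos("unknown stage name(s): ", paste(unknown, collapse = ", "))
  structure(list(out_dir = out_dir, input = input, citations = citations,
                 synthetic = synthetic, seed = as.integer(seed),
                 stages = stages, embedding = embedding,
                 n_keyword_clusters = as.integer(n_keyword_clusters),
                 n_method_clusters = as.integer(n_method_clusters),
                 level3_k = level3_k, filter = filter,
                 profile_cluster = profile_cluster,
                 ap_rounds = as.integer(ap_rounds),
                 top_k = as.integer(top_k)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(x$out_dir)) stop_semkos("malformed config: missing field 'out_dir'")
  args <- x[intersect(names(x), names(formals(run_config)))]
  do.call(run_config, args)
}

stage_paths <- function(cfg, stage, files) {
  file.path(cfg$out_dir, stage, files)
}

stage_key <- function(cfg, stage, params, upstream_hashes) {
  key_file <- tempfile()
  on.exit(unlink(key_file))
  writeLines(c(stage,
               as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                             digits = NA)),
               upstream_hashes), key_file)
  unname(tools::md5sum(key_file))
}

stage_cached <- function(cfg, stage, key, outputs) {
  key_path <- file.path(cfg$out_dir, stage, ".stage_key")
  file.exists(key_path) && identical(readLines(key_path, warn = FALSE), key) &&
    all(file.exists(outputs))
}

stage_commit <- function(cfg, stage, key) {
  writeLines(key, file.path(cfg$out_dir, stage, ".stage_key"))
}

log_event <- function(state, event) {
  line <- as.character(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA))
  cat(line, "\n", sep = "", file = state$log_con)
}

#' Run the pipeline
#'
#' Executes the requested stages in order, caching each stage's outputs under
#' `out_dir/<stage>/` keyed by a hash of the stage parameters and its
#' upstream artifact hashes; unchanged stages are skipped on re-runs. A
#' structured log (one JSON line per stage) is written to `out_dir/run.log`.
#'
#' @param cfg A `run_config` (or path to a JSON config).
#' @return The artifact manifest: list with `seed` and `files`, a named vector
#'   of md5 content hashes for every produced file. Also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in PIPELINE_STAGES)
    dir.create(file.path(cfg$out_dir, s), showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$files <- character(0)
  state$log_con <- file(file.path(cfg$out_dir, "run.log"), "w")
  on.exit(close(state$log_con))
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% cfg$stages) next
    run_stage(cfg, stage, state)
  }
  hashes <- tools::md5sum(state$files)
  names(hashes) <- substring(state$files, nchar(cfg$out_dir) + 2L)
  manifest <- list(seed = cfg$seed, files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

run_stage <- function(cfg, stage, state) {
  outputs <- switch(stage,
    corpus = stage_paths(cfg, stage, c("articles.jsonl", "citations.tsv")),
    lexicon = stage_paths(cfg, stage, "lexicon_full.tsv"),
    tokenize = stage_paths(cfg, stage,
                           c("lexicon_filtered.tsv", "streams.jsonl")),
    embed = stage_paths(cfg, stage, c("term_vectors.txt", "doc_vectors.txt")),
    cluster = stage_paths(cfg, stage,
                          c("keyword_tree.json", "keyword_tree.nwk",
                            "method_tree.json", "method_tree.nwk")),
    kos = stage_paths(cfg, stage, c("kos_keywords.tsv", "kos_methods.tsv")),
    correlate = stage_paths(cfg, stage,
                            c("correlation.tsv", "correlation_log.tsv",
                              "top_combinations.tsv")),
    powerlaw = stage_paths(cfg, stage, c("bins.csv", "fit.json")),
    articles = stage_paths(cfg, stage,
                           c("group.json", "rounds.json", "profile.tsv")))
  params <- cfg[setdiff(names(cfg), c("out_dir", "stages"))]
  upstream <- unname(tools::md5sum(state$files))
  key <- stage_key(cfg, stage, params, upstream)
  if (stage_cached(cfg, stage, key, outputs)) {
    log_event(state, list(stage = stage, cached = TRUE))
    state$files <- c(state$files, outputs)
    return(invisible())
  }
  compute_stage(cfg, stage, state, outputs)
  stage_commit(cfg, stage, key)
  state$files <- c(state$files, outputs)
  invisible()
}

state_articles <- function(cfg, state) {
  state$articles <- state$articles %||%
    read_articles_jsonl(stage_paths(cfg, "corpus", "articles.jsonl"))
  state$articles
}

state_streams <- function(cfg, state) {
  state$streams <- state$streams %||%
    read_streams_jsonl(stage_paths(cfg, "tokenize", "streams.jsonl"))
  state$streams
}

state_lexicon <- function(cfg, state) {
  state$flexicon <- state$flexicon %||%
    read_lexicon_tsv(stage_paths(cfg, "tokenize", "lexicon_filtered.tsv"))
  state$flexicon
}

state_vectors <- function(cfg, state) {
  if (is.null(state$vectors)) {
    tm <- read_word2vec_text(stage_paths(cfg, "embed", "term_vectors.txt"))
    dm <- read_word2vec_text(stage_paths(cfg, "embed", "doc_vectors.txt"))
    state$vectors <- normalize_vectors(new_vector_table(tm, dm))
  }
  state$vectors
}

state_trees <- function(cfg, state) {
  if (is.null(state$kwd_tree)) {
    state$kwd_tree <- import_tree_json(
      paste(readLines(stage_paths(cfg, "cluster", "keyword_tree.json")),
            collapse = ""))
    state$mtd_tree <- import_tree_json(
      paste(readLines(stage_paths(cfg, "cluster", "method_tree.json")),
            collapse = ""))
  }
  list(kwd = state$kwd_tree, mtd = state$mtd_tree)
}

state_kos <- function(cfg, state) {
  if (is.null(state$kwd_kos)) {
    trees <- state_trees(cfg, state)
    state$kwd_kos <- read_kos_tsv(stage_paths(cfg, "kos", "kos_keywords.tsv"),
                                  trees$kwd)
    state$mtd_kos <- read_kos_tsv(stage_paths(cfg, "kos", "kos_methods.tsv"),
                                  trees$mtd)
  }
  list(kwd = state$kwd_kos, mtd = state$mtd_kos)
}

state_citations <- function(cfg, state) {
  state$citations <- state$citations %||%
    read_citation_table(stage_paths(cfg, "corpus", "citations.tsv"))
  state$citations
}

compute_stage <- function(cfg, stage, state, outputs) {
  if (stage == "corpus") {
    if (is.null(cfg$input)) {
      spec <- do.call(planted_spec,
                      c(cfg$synthetic,
                        if (is.null(cfg$synthetic$seed)) list(seed = cfg$seed)))
      gen <- generate_corpus(spec)
      xml_dir <- file.path(cfg$out_dir, "corpus", "xml")
      write_corpus_jats(gen$articles, xml_dir)
      jsonlite::write_json(
        list(term_group = as.list(gen$truth$term_group),
             method_group = as.list(gen$truth$method_group),
             article_topic = as.list(gen$truth$article_topic),
             affinity_pair = as.list(gen$truth$affinity_pair)),
        file.path(cfg$out_dir, "corpus", "ground_truth.json"),
        auto_unbox = TRUE)
      articles <- read_jats_articles(
        xml_dir, citations = read_citation_table(file.path(xml_dir,
                                                           "citations.tsv")))
      file.copy(file.path(xml_dir, "citations.tsv"), outputs[2],
                overwrite = TRUE)
    } else {
      cit <- if (!is.null(cfg$citations)) read_citation_table(cfg$citations)
      articles <- read_jats_articles(cfg$input, citations = cit)
      write_citation_tsv(articles, outputs[2])
    }
    write_articles_jsonl(articles, outputs[1])
    state$articles <- articles
    log_event(state, list(stage = stage, cached = FALSE,
                          n_articles = length(articles)))
  } else if (stage == "lexicon") {
    lex <- build_lexicon(state_articles(cfg, state))
    write_lexicon_tsv(lex, outputs[1])
    state$lexicon <- lex
    log_event(state, list(stage = stage, cached = FALSE, n_terms = nrow(lex)))
  } else if (stage == "tokenize") {
    articles <- state_articles(cfg, state)
    lex <- state$lexicon %||%
      read_lexicon_tsv(stage_paths(cfg, "lexicon", "lexicon_full.tsv"))
    streams_full <- tokenize_corpus(articles, lex)
    lex <- set_corpus_counts(lex, streams_full)
    flex <- do.call(filter_lexicon, c(list(lexicon = lex), cfg$filter))
    streams <- tokenize_corpus(articles, flex)
    write_lexicon_tsv(flex, outputs[1])
    write_streams_jsonl(streams, outputs[2])
    state$flexicon <- flex
    state$streams <- streams
    log_event(state, list(stage = stage, cached = FALSE,
                          n_terms_kept = nrow(flex)))
  } else if (stage == "embed") {
    emb_cfg <- do.call(embedding_config,
                       c(cfg$embedding,
                         if (is.null(cfg$embedding$random_seed))
                           list(random_seed = cfg$seed)))
    tab <- train_embeddings(state_streams(cfg, state), emb_cfg)
    write_word2vec_text(tab$term_vectors, outputs[1])
    write_word2vec_text(tab$doc_vectors, outputs[2])
    state$vectors <- normalize_vectors(tab)
    log_event(state, list(stage = stage, cached = FALSE,
                          n_vectors = nrow(tab$term_vectors)))
  } else if (stage == "cluster") {
    tab <- state_vectors(cfg, state)
    lex <- state_lexicon(cfg, state)
    build_one <- function(kind, json_path, nwk_path) {
      ids <- intersect(lex$term_id[lex$kind == kind],
                       rownames(tab$term_vectors))
      tr <- agglomerate_average_linkage(pairwise_distances(tab, ids))
      validate_merge_tree(tr)
      writeLines(export_tree(tr, "json"), json_path)
      writeLines(export_tree(tr, "newick"), nwk_path)
      tr
    }
    state$kwd_tree <- build_one("keyword", outputs[1], outputs[2])
    state$mtd_tree <- build_one("method", outputs[3], outputs[4])
    log_event(state, list(stage = stage, cached = FALSE,
                          kwd_leaves = state$kwd_tree$n_leaves,
                          mtd_leaves = state$mtd_tree$n_leaves))
  } else if (stage == "kos") {
    trees <- state_trees(cfg, state)
    tab <- state_vectors(cfg, state)
    mk <- function(tree, k, prefix) {
      ks <- kos_from_cut(tree, min(k, tree$n_leaves), prefix)
      if (length(ks$annotations) >= 2L)
        ks <- regroup_level3(ks, tab, k = cfg$level3_k)
      ks
    }
    state$kwd_kos <- mk(trees$kwd, cfg$n_keyword_clusters, "kwd_cluster")
    state$mtd_kos <- mk(trees$mtd, cfg$n_method_clusters, "mtd_cluster")
    write_kos_tsv(state$kwd_kos, outputs[1])
    write_kos_tsv(state$mtd_kos, outputs[2])
    log_event(state, list(stage = stage, cached = FALSE,
                          kwd_clusters = length(state$kwd_kos$annotations),
                          mtd_clusters = length(state$mtd_kos$annotations)))
  } else if (stage == "correlate") {
    ks <- state_kos(cfg, state)
    m <- correlation_matrix(state_streams(cfg, state), ks$kwd, ks$mtd,
                            state_citations(cfg, state))
    write_matrix_tsv(m, outputs[1])
    write_matrix_tsv(log_heatmap_matrix(m), outputs[2])
    top <- rank_top_combinations(m, cfg$top_k)
    write.table(top, outputs[3], sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    state$correlation <- m
    log_event(state, list(stage = stage, cached = FALSE,
                          matrix_mass = sum(m)))
  } else if (stage == "powerlaw") {
    m <- state$correlation %||% {
      ks <- state_kos(cfg, state)
      correlation_matrix(state_streams(cfg, state), ks$kwd, ks$mtd,
                         state_citations(cfg, state))
    }
    bins <- bin_correlation_counts(m)
    write.table(bins, outputs[1], sep = ",", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    fit <- tryCatch(fit_power_law(bins), error = function(e)
      list(exponent = NA, intercept = NA, r_squared = NA,
           note = conditionMessage(e)))
    jsonlite::write_json(fit, outputs[2], auto_unbox = TRUE, digits = NA,
                         na = "null")
    log_event(state, list(stage = stage, cached = FALSE,
                          binned = sum(bins$count)))
  } else if (stage == "articles") {
    ks <- state_kos(cfg, state)
    streams <- state_streams(cfg, state)
    tab <- state_vectors(cfg, state)
    name <- cfg$profile_cluster
    if (identical(name, "auto")) {
      sizes <- vapply(kos_level2_names(ks$kwd), function(nm)
        length(kos_members(ks$kwd, nm)), integer(1))
      name <- names(sizes)[order(-sizes, names(sizes))][1]
    }
    group <- retrieve_articles(ks$kwd, name, streams)
    dv <- tab$doc_vectors[intersect(group$members, rownames(tab$doc_vectors)),
                          , drop = FALSE]
    rounds <- multiround_cluster(dv, rounds = cfg$ap_rounds)
    prof <- profile_article_group(group, streams, ks$kwd, ks$mtd,
                                  state_citations(cfg, state), k = cfg$top_k)
    jsonlite::write_json(list(group_id = group$group_id,
                              members = group$members),
                         outputs[1], auto_unbox = TRUE)
    jsonlite::write_json(
      list(n_clusters = vapply(rounds$rounds, function(r) r$n_clusters,
                               integer(1)),
           assignment = as.list(rounds$assignment)),
      outputs[2], auto_unbox = TRUE)
    write_profile_tsv(prof, outputs[3])
    log_event(state, list(stage = stage, cached = FALSE,
                          group_size = length(group$members)))
  }
}
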