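# Shared fixtures: tiny lexicons, article builders, random distance matrices.

make_lexicon <- function(keywords = character(), methods = character()) {
  df <- rbind(
    if (length(keywords))
      data.frame(term_id = paste0("kwd", seq_along(keywords)), kind = "keyword",
                 surface = normalize_surface(keywords),
                 source_count = rev(seq_along(keywords)) + 10L,
                 corpus_count = 100L, stringsAsFactors = FALSE),
    if (length(methods))
      data.frame(term_id = paste0("mtd", seq_along(methods)), kind = "method",
                 surface = normalize_surface(methods),
                 source_count = rev(seq_along(methods)) + 10L,
                 corpus_count = 100L, stringsAsFactors = FALSE))
  structure(df, class = c("term_lexicon", "data.frame"))
}

make_article <- function(id, keywords = character(), subtitles = character(),
                         body = "", title = "a title", citations = 0L,
                         methods_title = "Methods") {
  sections <- list()
  if (length(subtitles) || nzchar(body))
    sections <- list(section_record(methods_title, subtitles,
                                    body = ""),
                     section_record("Results", body = body))
  article_record(id, title = title, sections = sections,
                 author_keywords = keywords, citation_count = citations)
}

random_dist_matrix <- function(n) {
  d <- matrix(runif(n * n, 0.1, 5), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# unit vectors spread over coordinate directions with small noise
unit_vectors <- function(ids, dim = 8, center = NULL, noise = 0.05) {
  v <- matrix(rnorm(length(ids) * dim, sd = noise), length(ids), dim)
  if (is.null(center)) center <- diag(dim)[rep_len(seq_len(dim), length(ids)), ]
  v <- v + center
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- ids
  v
}

vector_table_of <- function(term_vectors,
                            doc_vectors = term_vectors[0, , drop = FALSE]) {
  structure(list(term_vectors = term_vectors, doc_vectors = doc_vectors,
                 dimension = ncol(term_vectors)), class = "vector_table")
}

# JATS fixture written as raw XML text
write_jats_fixture <- function(path, articles_xml) {
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", articles_xml),
             path)
  path
}

jats_article_xml <- function(id, title = "T", keywords = character(),
                             sections = "") {
  kwd <- if (length(keywords))
    paste0("<kwd-group>",
           paste0("<kwd>", keywords, "</kwd>", collapse = ""),
           "</kwd-group>") else ""
  paste0("<article><front><article-meta>",
         "<article-id pub-id-type=\"pmc\">", id, "</article-id>",
         "<title-group><article-title>", title, "</article-title></title-group>",
         kwd, "</article-meta></front><body>", sections, "</body></article>")
}
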