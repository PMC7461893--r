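# Keyword and method lexicons. Terms are normalized surfaces with rank-based
# ids: the most frequent keyword is kwd1, the most frequent method mtd1.
# Surfaces occurring in both lists are kept only as methods so that the
# downstream keyword-by-method co-occurrence has disjoint vocabularies.

#' Normalize a term surface
#'
#' Lowercases, strips leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces.
#'
#' @param raw Character vector of raw surfaces.
#' @return Character vector of normalized surfaces.
#' @export
normalize_surface <- function(raw) {
  gsub("\\s+", " ", trimws(tolower(as.character(raw))))
}

new_lexicon <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("term_lexicon", "data.frame"))
}

#' Build the keyword/method lexicon from a corpus
#'
#' Counts normalized keyword surfaces over the articles' keyword sections and
#' normalized method surfaces over methods-section subtitles
#' ([extract_method_subtitles()]). Surfaces present in both lists are deleted
#' from the keyword list and retained only as methods. Within each kind,
#' term ids are assigned by descending source count (`kwd1`, `kwd2`, ...;
#' `mtd1`, ...), ties broken lexicographically by surface.
#'
#' @param articles List of `article_record` objects.
#' @return A `term_lexicon`: data frame with columns `term_id`, `kind`,
#'   `surface`, `source_count`, `corpus_count` (initially `NA`).
#' @export
build_lexicon <- function(articles) {
  kw <- normalize_surface(unlist(lapply(articles, extract_author_keywords)))
  mt <- normalize_surface(unlist(lapply(articles, extract_method_subtitles)))
  kw <- kw[nzchar(kw)]; mt <- mt[nzchar(mt)]
  kw_tab <- table(kw); mt_tab <- table(mt)
  kw_tab <- kw_tab[!(names(kw_tab) %in% names(mt_tab))]  # dedup: keep as method
  rank_kind <- function(tab, prefix) {
    if (length(tab) == 0L)
      return(data.frame(term_id = character(), kind = character(),
                        surface = character(), source_count = integer(),
                        corpus_count = integer(), stringsAsFactors = FALSE))
    o <- order(-as.integer(tab), names(tab))
    data.frame(term_id = paste0(prefix, seq_along(o)),
               kind = if (prefix == "kwd") "keyword" else "method",
               surface = names(tab)[o],
               source_count = as.integer(tab)[o],
               corpus_count = NA_integer_, stringsAsFactors = FALSE)
  }
  new_lexicon(rbind(rank_kind(kw_tab, "kwd"), rank_kind(mt_tab, "mtd")))
}

#' Count lexicon term occurrences in tokenized streams
#'
#' @param streams List of token streams from [tokenize_corpus()].
#' @return Named integer vector, `term_id -> total occurrences`.
#' @export
corpus_term_counts <- function(streams) {
  ids <- unlist(lapply(streams, function(s) s$term_id), use.names = FALSE)
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Fill in corpus counts on a lexicon
#'
#' @param lexicon A `term_lexicon`.
#' @param streams Token streams over the same lexicon.
#' @return The lexicon with `corpus_count` populated (0 for unseen terms).
#' @export
set_corpus_counts <- function(lexicon, streams) {
  counts <- corpus_term_counts(streams)
  cc <- counts[lexicon$term_id]
  cc[is.na(cc)] <- 0L
  lexicon$corpus_count <- as.integer(cc)
  lexicon
}

#' Apply the frequency filters to a lexicon
#'
#' Keywords are kept iff they occur more than 5 times in keyword sections and
#' more than 10 times in the tokenized corpus; methods iff more than 2 times
#' as methods subtitles and more than 10 times in the corpus (strict
#' inequalities). Ranks and term ids are NOT reassigned after filtering, so
#' ids remain stable across the filter.
#'
#' @param lexicon A `term_lexicon` (its `corpus_count` is used unless
#'   `corpus_counts` is given).
#' @param corpus_counts Optional named counts, `surface -> occurrences in the
#'   tokenized corpus`, as produced by tokenizing with the unfiltered lexicon.
#' @param keyword_source_min,method_source_min,corpus_min Strict lower
#'   thresholds (kept iff count > threshold).
#' @return The filtered `term_lexicon`.
#' @export
filter_lexicon <- function(lexicon, corpus_counts = NULL,
                           keyword_source_min = 5L, method_source_min = 2L,
                           corpus_min = 10L) {
  cc <- lexicon$corpus_count
  if (!is.null(corpus_counts)) {
    cc <- as.integer(corpus_counts[lexicon$surface])
    cc[is.na(cc)] <- 0L
  }
  if (anyNA(cc))
    stop_semkos("corpus counts missing; tokenize with the unfiltered lexicon first")
  keep <- ifelse(lexicon$kind == "keyword",
                 lexicon$source_count > keyword_source_min,
                 lexicon$source_count > method_source_min) & cc > corpus_min
  out <- lexicon[keep, , drop = FALSE]
  out$corpus_count <- cc[keep]
  new_lexicon(out)
}

#' Write / read a lexicon as TSV
#'
#' Columns: `term_id`, `kind`, `surface`, `source_count`, `corpus_count`.
#'
#' @param lexicon A `term_lexicon`.
#' @param path File path.
#' @return `write_lexicon_tsv()` returns `path` invisibly; `read_lexicon_tsv()`
#'   a `term_lexicon`.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "integer", "integer"))
  new_lexicon(df)
}
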