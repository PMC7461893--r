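# Reading JATS/NXML article files into article records, and extracting the two
# raw term streams the KOS is built from: author keywords and the subtitles of
# methods-like sections. Citation counts (the article weight W used by the
# co-occurrence statistics) come from an external side table because JATS full
# text does not carry cited-by counts.

#' Construct an article record
#'
#' An article record is the package's in-memory representation of one JATS
#' article: identifier, title, ordered sections, author keywords, and a
#' non-negative citation count used as the article weight in citation-weighted
#' statistics.
#'
#' @param article_id Unique opaque identifier (character scalar).
#' @param title Article title.
#' @param sections List of section records (see [section_record()]).
#' @param author_keywords Character vector of raw author keywords, in document
#'   order; multiple keyword groups are concatenated.
#' @param citation_count Non-negative integer citation count (defaults to 0).
#' @return An object of class `article_record`.
#' @export
article_record <- function(article_id, title = "", sections = list(),
                           author_keywords = character(), citation_count = 0L) {
  stopifnot(is.character(article_id), length(article_id) == 1L, nzchar(article_id))
  citation_count <- as.integer(citation_count)
  if (is.na(citation_count) || citation_count < 0L)
    stop_semkos("citation_count must be a non-negative integer for article ", article_id)
  structure(
    list(article_id = article_id, title = as.character(title),
         sections = sections,
         author_keywords = as.character(author_keywords),
         citation_count = citation_count),
    class = "article_record")
}

#' Construct a section record
#'
#' @param title Section title.
#' @param subtitles Titles of the section's immediate (first-level) subsections,
#'   in document order.
#' @param body Concatenated paragraph text of the section.
#' @return An object of class `section_record`.
#' @export
section_record <- function(title = "", subtitles = character(), body = "") {
  structure(list(title = as.character(title),
                 subtitles = as.character(subtitles),
                 body = as.character(body)),
            class = "section_record")
}

#' Read JATS/NXML articles
#'
#' Parses one file or a directory of files in the JATS article dialect (as
#' distributed by PubMed Central full-text exports) into article records. Each
#' `<article>` element yields one record. Missing keyword groups yield empty
#' `author_keywords`; citation counts default to 0 unless supplied through
#' `citations` (see [read_citation_table()]).
#'
#' @param path A file, or a directory whose `.xml`/`.nxml` files are read.
#' @param citations Optional named integer vector, `article_id -> citations`.
#' @return List of `article_record` objects.
#' @export
read_jats_articles <- function(path, citations = NULL) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(xml|nxml)$", full.names = TRUE))
  } else {
    if (!file.exists(path)) stop_semkos("no such file or directory: ", path)
    path
  }
  if (length(files) == 0L) stop_semkos("no .xml/.nxml files found under ", path)
  records <- list()
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f), error = function(e)
      stop_semkos("malformed XML in '", f, "': ", conditionMessage(e)))
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, "//article")
    if (length(nodes) == 0L) next
    for (i in seq_along(nodes)) {
      records[[length(records) + 1L]] <-
        parse_article_node(nodes[[i]], fallback_id = paste0(basename(f), "#", i))
    }
  }
  ids <- vapply(records, function(r) r$article_id, character(1))
  if (anyDuplicated(ids))
    stop_semkos("duplicate article_id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(citations)) {
    for (k in seq_along(records)) {
      w <- unname(citations[records[[k]]$article_id])
      if (length(w) == 1L && !is.na(w))
        records[[k]]$citation_count <- as.integer(w)
    }
  }
  records
}

parse_article_node <- function(node, fallback_id) {
  id_node <- xml2::xml_find_first(
    node, "./front/article-meta/article-id[@pub-id-type='pmc']")
  if (is.na(id_node))
    id_node <- xml2::xml_find_first(node, ".//article-meta/article-id")
  id <- if (is.na(id_node)) fallback_id else xml2::xml_text(id_node)
  title_node <- xml2::xml_find_first(node, ".//article-meta//article-title")
  title <- if (is.na(title_node)) "" else xml2::xml_text(title_node)
  kwds <- xml2::xml_text(xml2::xml_find_all(node, ".//kwd-group/kwd"))
  secs <- lapply(xml2::xml_find_all(node, "./body/sec"), function(sec) {
    t_node <- xml2::xml_find_first(sec, "./title")
    subt <- xml2::xml_text(xml2::xml_find_all(sec, "./sec/title"))
    body <- paste(xml2::xml_text(xml2::xml_find_all(sec, ".//p")), collapse = "\n")
    section_record(title = if (is.na(t_node)) "" else xml2::xml_text(t_node),
                   subtitles = subt, body = body)
  })
  article_record(article_id = id, title = title, sections = secs,
                 author_keywords = kwds, citation_count = 0L)
}

#' Read a citation side table
#'
#' A two-column TSV with header `article_id<TAB>citations` mapping article ids
#' to non-negative citation counts.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector.
#' @export
read_citation_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("article_id", "citations") %in% names(df)))
    stop_semkos("citation table must have columns 'article_id' and 'citations'")
  w <- as.integer(df$citations)
  if (anyNA(w) || any(w < 0L)) stop_semkos("citations must be non-negative integers")
  setNames(w, df$article_id)
}

#' Is a section title a methods-section title?
#'
#' True iff the lowercased title contains the substring "method" or
#' "procedure", so "Methods", "Experimental procedures" and "Methodology" all
#' match.
#'
#' @param title Character vector of section titles.
#' @return Logical vector.
#' @export
is_methods_section_title <- function(title) {
  t <- tolower(as.character(title))
  grepl("method", t, fixed = TRUE) | grepl("procedure", t, fixed = TRUE)
}

#' Extract method-name subtitles from an article
#'
#' Concatenates the first-level subsection titles of every section whose title
#' satisfies [is_methods_section_title()], in document order. These subtitles
#' typically name experimental methods ("Statistical analysis",
#' "Immunohistochemistry", ...) and are the raw method-term stream.
#'
#' @param article An `article_record`.
#' @return Character vector (possibly empty).
#' @export
extract_method_subtitles <- function(article) {
  out <- character()
  for (sec in article$sections)
    if (is_methods_section_title(sec$title)) out <- c(out, sec$subtitles)
  out
}

#' Extract raw author keywords from an article
#'
#' @param article An `article_record`.
#' @return Character vector of raw keyword strings in document order
#'   (duplicates kept; they are occurrence counts downstream).
#' @export
extract_author_keywords <- function(article) {
  article$author_keywords
}

#' Full text of an article for tokenization
#'
#' Concatenates title, author keywords, and for each section its title,
#' subtitles and body, separated by newlines (newlines act as sentence
#' boundaries for term recognition).
#'
#' @param article An `article_record`.
#' @return A single character string.
#' @export
article_text <- function(article) {
  parts <- c(article$title, article$author_keywords)
  for (sec in article$sections)
    parts <- c(parts, sec$title, sec$subtitles, sec$body)
  paste(parts[nzchar(parts)], collapse = "\n")
}

#' Write / read article records as JSON-lines
#'
#' One UTF-8 JSON object per line; round-tripping yields identical records.
#'
#' @param articles List of `article_record` objects.
#' @param path Output (input) file path.
#' @return `write_articles_jsonl()` returns `path` invisibly;
#'   `read_articles_jsonl()` returns a list of `article_record` objects.
#' @export
write_articles_jsonl <- function(articles, path) {
  lines <- vapply(articles, function(a) {
    jsonlite::toJSON(list(
      article_id = a$article_id, title = a$title,
      sections = lapply(a$sections, function(s)
        list(title = s$title, subtitles = as.list(s$subtitles), body = s$body)),
      author_keywords = as.list(a$author_keywords),
      citation_count = a$citation_count), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_articles_jsonl
#' @export
read_articles_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    article_record(
      article_id = x$article_id, title = x$title,
      sections = lapply(x$sections, function(s)
        section_record(s$title, unlist(s$subtitles) %||% character(), s$body)),
      author_keywords = unlist(x$author_keywords) %||% character(),
      citation_count = x$citation_count)
  })
}
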