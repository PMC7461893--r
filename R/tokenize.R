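# Longest-phrase-first term recognition. Text is scanned left to right over
# word boundaries; at each unconsumed position the longest lexicon phrase
# starting there is emitted and its words consumed, so shorter phrases nested
# inside an emitted phrase ("short-term memory" inside "visual short-term
# memory") are not emitted. Matches do not cross sentence boundaries, and all
# words not recognized as lexicon terms are dropped from the stream.

# Words are runs of alphanumerics with internal hyphens kept ("short-term" is
# one word); all other punctuation and whitespace delimits words.
WORD_RE <- "[[:alnum:]]+(?:-[[:alnum:]]+)*"
SENTENCE_RE <- "[^.?!\n]+"

split_words <- function(text) {
  m <- gregexpr(WORD_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(words = character(), start = integer(), end = integer()))
  len <- attr(m, "match.length")
  list(words = tolower(substring(text, m, m + len - 1L)),
       start = as.integer(m), end = as.integer(m + len - 1L))
}

# Phrase index: environment keyed by first word; each entry holds the phrases
# starting with that word, longest first. Attached to the lexicon so repeated
# tokenization compiles it once.
compile_lexicon_index <- function(lexicon) {
  idx <- attr(lexicon, "phrase_index")
  if (!is.null(idx)) return(idx)
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(lexicon)))
  words_per_term <- lapply(lexicon$surface, function(s) split_words(s)$words)
  keep <- lengths(words_per_term) > 0L
  for (i in which(keep)) {
    w <- words_per_term[[i]]
    first <- w[1]
    entry <- if (exists(first, envir = env, inherits = FALSE))
      get(first, envir = env) else list(ids = character(), lens = integer(),
                                        rest = list())
    entry$ids <- c(entry$ids, lexicon$term_id[i])
    entry$lens <- c(entry$lens, length(w))
    entry$rest <- c(entry$rest, list(w[-1]))
    assign(first, entry, envir = env)
  }
  for (first in ls(env)) {
    entry <- get(first, envir = env)
    o <- order(-entry$lens, entry$ids)
    assign(first, list(ids = entry$ids[o], lens = entry$lens[o],
                       rest = entry$rest[o]), envir = env)
  }
  idx <- list(env = env, first_words = ls(env))
  idx
}

lexicon_with_index <- function(lexicon) {
  attr(lexicon, "phrase_index") <- compile_lexicon_index(lexicon)
  lexicon
}

new_token_stream <- function(term_id, start, end, article_id = NA_character_) {
  structure(data.frame(term_id = as.character(term_id),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            article_id = article_id,
            class = c("token_stream", "data.frame"))
}

#' Recognize lexicon terms in text (longest phrase first)
#'
#' Scans each sentence (sentences are delimited by `.`, `?`, `!` and newlines;
#' phrase matches never cross them) left to right. At each position the
#' longest lexicon phrase starting there is emitted as one token and its words
#' are consumed; scanning resumes after the emitted phrase, so matches never
#' overlap. Words not recognized as lexicon terms are discarded.
#'
#' @param text A character string.
#' @param lexicon A `term_lexicon`.
#' @param article_id Optional id recorded on the stream.
#' @return A `token_stream`: data frame with columns `term_id`, `start`, `end`
#'   (1-based character spans into `text`), with attribute `article_id`.
#' @export
recognize_terms <- function(text, lexicon, article_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  idx <- compile_lexicon_index(lexicon)
  out_id <- out_s <- out_e <- list()
  sm <- gregexpr(SENTENCE_RE, text, perl = TRUE)[[1]]
  if (sm[1] != -1L) {
    slen <- attr(sm, "match.length")
    sents <- substring(text, sm, sm + slen - 1L)
    wm <- gregexpr(WORD_RE, sents, perl = TRUE)
    # flatten all words of the article, remembering their sentence so phrase
    # matches never cross a sentence boundary
    nwords <- vapply(wm, function(m) if (m[1] == -1L) 0L else length(m),
                     integer(1))
    sent_of <- rep.int(seq_along(sents), nwords)
    off <- rep.int(as.integer(sm) - 1L, nwords)
    wstart <- off + unlist(wm[nwords > 0L], use.names = FALSE)
    wend <- wstart +
      unlist(lapply(wm[nwords > 0L], attr, "match.length"),
             use.names = FALSE) - 1L
    words <- tolower(substring(text, wstart, wend))
    n <- length(words)
    cand <- which(words %in% idx$first_words)
    consumed_upto <- 0L
    for (i in cand) {
      if (i <= consumed_upto) next  # inside an emitted phrase
      entry <- get(words[i], envir = idx$env)
      for (j in seq_along(entry$ids)) {
        L <- entry$lens[j]
        if (i + L - 1L > n || sent_of[i + L - 1L] != sent_of[i]) next
        if (L == 1L || identical(words[seq.int(i + 1L, i + L - 1L)],
                                 entry$rest[[j]])) {
          k <- length(out_id) + 1L
          out_id[[k]] <- entry$ids[j]
          out_s[[k]] <- wstart[i]
          out_e[[k]] <- wend[i + L - 1L]
          consumed_upto <- i + L - 1L
          break
        }
      }
    }
  }
  new_token_stream(unlist(out_id) %||% character(),
                   unlist(out_s) %||% integer(),
                   unlist(out_e) %||% integer(), article_id)
}

#' Tokenize a corpus of articles
#'
#' Applies [recognize_terms()] to each article's concatenated text
#' ([article_text()]). Deterministic: repeated runs on identical input yield
#' identical streams.
#'
#' @param articles List of `article_record` objects.
#' @param lexicon A `term_lexicon`.
#' @return Named list of `token_stream` objects, one per article.
#' @export
tokenize_corpus <- function(articles, lexicon) {
  lexicon <- lexicon_with_index(lexicon)
  streams <- lapply(articles, function(a)
    recognize_terms(article_text(a), lexicon, article_id = a$article_id))
  names(streams) <- vapply(articles, function(a) a$article_id, character(1))
  streams
}

#' Write / read token streams as JSON-lines
#'
#' One line per article: `{"article_id": ..., "tokens": [[term_id, start,
#' end], ...]}`.
#'
#' @param streams List of `token_stream` objects.
#' @param path File path.
#' @return `write_streams_jsonl()` returns `path` invisibly;
#'   `read_streams_jsonl()` a named list of `token_stream` objects.
#' @export
write_streams_jsonl <- function(streams, path) {
  lines <- vapply(streams, function(s) {
    toks <- lapply(seq_len(nrow(s)), function(i)
      list(s$term_id[i], s$start[i], s$end[i]))
    jsonlite::toJSON(list(article_id = attr(s, "article_id"), tokens = toks),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_streams_jsonl
#' @export
read_streams_jsonl <- function(path) {
  streams <- lapply(readLines(path, encoding = "UTF-8"), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    ids <- vapply(x$tokens, function(t) as.character(t[[1]]), character(1))
    st <- vapply(x$tokens, function(t) as.integer(t[[2]]), integer(1))
    en <- vapply(x$tokens, function(t) as.integer(t[[3]]), integer(1))
    new_token_stream(ids, st, en, x$article_id)
  })
  names(streams) <- vapply(streams, function(s) attr(s, "article_id"), character(1))
  streams
}
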