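# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# UPGMA by recomputing every inter-cluster average from the original matrix at
# every step (O(n^3)), with the (min label, max label) tie-break.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)   # leaf index sets
  labels <- seq_len(n)
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0))
  for (k in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        key_new <- c(min(labels[i], labels[j]), max(labels[i], labels[j]))
        better <- avg < best ||
          (avg == best && (key_new[1] < key_best[1] ||
                           (key_new[1] == key_best[1] && key_new[2] < key_best[2])))
        if (is.na(bi) || better) {
          best <- avg; bi <- i; bj <- j; key_best <- key_new
        }
      }
    }
    merges <- rbind(merges,
                    data.frame(a = min(labels[bi], labels[bj]),
                               b = max(labels[bi], labels[bj]), height = best))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    labels[bi] <- n + k
    clusters[[bj]] <- NULL
    labels <- labels[-bj]
  }
  merges
}

# Greedy longest-first tokenizer over word lists, sentence by sentence;
# returns the matched surfaces in order.
oracle_tokenize <- function(text, surfaces) {
  word_lists <- lapply(strsplit(surfaces, " ", fixed = TRUE), tolower)
  ord <- order(-lengths(word_lists))
  out <- character(0)
  for (sent in strsplit(text, "[.?!\n]+")[[1]]) {
    words <- tolower(regmatches(sent,
      gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", sent, perl = TRUE))[[1]])
    pos <- 1L
    while (pos <= length(words)) {
      hit <- 0L
      for (oi in ord) {
        wl <- word_lists[[oi]]
        if (pos + length(wl) - 1L <= length(words) &&
            identical(words[pos:(pos + length(wl) - 1L)], wl)) {
          out <- c(out, surfaces[oi])
          hit <- length(wl)
          break
        }
      }
      pos <- pos + max(hit, 1L)
    }
  }
  out
}

# random phrase lexicon over a small word alphabet, for tokenizer fuzzing
random_phrase_lexicon <- function(alphabet = letters[1:6], max_len = 3,
                                  n_phrases = 5) {
  surfaces <- unique(vapply(seq_len(n_phrases), function(i)
    paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
          collapse = " "), character(1)))
  make_lexicon(keywords = surfaces)
}

random_word_text <- function(alphabet = letters[1:6], n_words = 30) {
  words <- sample(alphabet, n_words, replace = TRUE)
  stops <- runif(n_words) < 0.1
  paste0(paste0(words, ifelse(stops, ".", "")), collapse = " ")
}
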