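#' Load an easy-word list
#'
#' Reads a plain-text word list (one lowercase word per line, `#` comments
#' allowed) of the kind used by the Dale-Chall formula: words a young reader
#' is assumed to know. Words absent from the list count as "hard".
#'
#' The packaged default (`easy_words_synthetic.txt`) is a hand-written
#' approximation of such a list, not the copyrighted New Dale-Chall list;
#' supply your own file for production scoring against the genuine list.
#'
#' @param path Path to a word-list file, or `NULL` for the packaged default.
#' @return Character vector of unique lowercase words.
#' @export
load_easy_words <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pemread_cache$easy_words)) return(.pemread_cache$easy_words)
    path <- system.file("extdata", "easy_words_synthetic.txt",
                        package = "pemread", mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  words <- tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
  words <- unique(words)
  if (length(words) == 0L) {
    stop_pemread("easy-word list is empty", "pemread_config_error")
  }
  if (default) .pemread_cache$easy_words <- words
  words
}

#' Load a syllable lexicon
#'
#' Reads a tab-separated pronunciation lexicon (`word<TAB>syllables`) used to
#' override the vowel-group heuristic for words with irregular
#' syllabification (mostly vowel hiatus, e.g. "idea", "period"). Words not in
#' the lexicon fall back to the heuristic in [count_syllables()].
#'
#' @param path Path to a lexicon file, or `NULL` for the packaged default.
#' @return Named integer vector: names are lowercase words, values counts.
#' @export
load_syllable_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pemread_cache$lexicon)) return(.pemread_cache$lexicon)
    path <- system.file("extdata", "syllable_lexicon.tsv",
                        package = "pemread", mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lex <- vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  names(lex) <- tolower(vapply(parts, `[[`, character(1), 1L))
  if (default) .pemread_cache$lexicon <- lex
  lex
}

#' Normalize raw document text
#'
#' Strips residual markup tags, removes bullet markers at line starts, and
#' collapses all whitespace runs (including blank lines) to single spaces.
#' Alphabetic content of retained sentences is never altered.
#'
#' @param raw A length-1 character string.
#' @return Cleaned single-line string.
#' @export
clean_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw)) stop_pemread("document text is NA", "pemread_empty_document")
  txt <- gsub("<[^>]+>", " ", raw)
  # bullet/list markers at the start of a line
  txt <- gsub("(^|\n)[[:space:]]*[-*•·]+[[:space:]]+", "\\1", txt)
  txt <- gsub("[[:space:]]+", " ", txt)
  txt <- trimws(txt)
  if (!nzchar(txt)) {
    stop_pemread("document is empty after cleaning", "pemread_empty_document")
  }
  txt
}

# Abbreviations whose trailing period must not end a sentence.
.abbrev <- c("dr", "mr", "mrs", "ms", "prof", "st", "vs", "etc", "fig",
             "approx", "dept", "jr", "sr", "no")

#' Split cleaned text into sentences
#'
#' Sentences end at `.`, `!` or `?` (possibly followed by closing quotes or
#' brackets). Periods after a small list of common abbreviations ("Dr.",
#' "e.g.", ...) are protected. Text with no terminal punctuation is returned
#' as a single sentence; fragments with no alphanumeric content are dropped.
#'
#' @param text Cleaned non-empty text (see [clean_text()]).
#' @return Character vector of sentence strings, in order.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) {
    stop_pemread("cannot segment empty text", "pemread_empty_document")
  }
  guard <- "\x01"
  prot <- text
  # multi-dot abbreviations first
  prot <- gsub("(?i)\\be\\.g\\.", paste0("e", guard, "g", guard), prot, perl = TRUE)
  prot <- gsub("(?i)\\bi\\.e\\.", paste0("i", guard, "e", guard), prot, perl = TRUE)
  pat <- paste0("(?i)\\b(", paste(.abbrev, collapse = "|"), ")\\.")
  prot <- gsub(pat, paste0("\\1", guard), prot, perl = TRUE)

  m <- regmatches(prot, gregexpr(
    "[^.!?]+[.!?]+[\"'”’)\\]]*|[^.!?]+$", prot, perl = TRUE))[[1]]
  if (length(m) == 0L) m <- prot
  m <- gsub(guard, ".", m, fixed = TRUE)
  m <- trimws(m)
  m <- m[grepl("[[:alnum:]]", m)]
  if (length(m) == 0L) {
    stop_pemread("text contains no words", "pemread_empty_document")
  }
  m
}

#' Tokenize a sentence into words
#'
#' Words are maximal non-space runs with leading/trailing punctuation
#' stripped; internal apostrophes and hyphens are kept (a hyphenated word is
#' one word). Empty tokens are dropped.
#'
#' @param sentence A sentence string.
#' @return Character vector of word tokens.
#' @export
tokenize_words <- function(sentence) {
  raw <- unlist(strsplit(sentence, "[[:space:]]+"), use.names = FALSE)
  tok <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", raw)
  tok[nzchar(tok)]
}

#' Count syllables per word
#'
#' Looks each word up in a pronunciation lexicon first; otherwise applies a
#' vowel-group heuristic: count maximal runs of `aeiouy`, subtract one for a
#' silent final `e` (also in `-es`/`-ed` endings where the `e` is silent,
#' e.g. "makes", "worked", but not "wishes", "wanted" or consonant-`le` as in
#' "table"), with a floor of one syllable. Hyphenated words are summed over
#' their parts; purely numeric tokens count one syllable per digit.
#'
#' @param words Character vector of word tokens.
#' @param lexicon Named integer vector from [load_syllable_lexicon()].
#' @return Integer vector of syllable counts, all >= 1.
#' @export
count_syllables <- function(words, lexicon = load_syllable_lexicon()) {
  if (length(words) == 0L) return(integer(0))
  w <- tolower(words)
  w <- gsub("'", "", w, fixed = TRUE)

  out <- rep(NA_integer_, length(w))

  # lexicon lookup on the whole token
  hit <- match(w, names(lexicon))
  out[!is.na(hit)] <- unname(lexicon[hit[!is.na(hit)]])

  # hyphenated words: sum over parts
  todo <- is.na(out) & grepl("-", w, fixed = TRUE)
  if (any(todo)) {
    parts <- strsplit(w[todo], "-", fixed = TRUE)
    out[todo] <- vapply(parts, function(p) {
      p <- p[nzchar(p)]
      if (length(p) == 0L) 1L else sum(count_syllables(p, lexicon))
    }, integer(1))
  }

  todo <- which(is.na(out))
  if (length(todo)) {
    wl <- gsub("[^a-z]", "", w[todo])
    # tokens with no letters: one syllable per digit, floor 1
    noalpha <- !nzchar(wl)
    if (any(noalpha)) {
      ndig <- nchar(gsub("[^0-9]", "", w[todo][noalpha]))
      out[todo[noalpha]] <- pmax(1L, ndig)
    }
    alpha <- !noalpha
    if (any(alpha)) {
      v <- wl[alpha]
      marked <- gsub("[aeiouy]+", "\x01", v)
      groups <- nchar(gsub("[^\x01]", "", marked))
      silent <- (grepl("[^aeiouy]e$", v) & !grepl("[^aeiouy]le$", v)) |
        (grepl("[^aeiouyscxzgh]es$", v) & !grepl("[^aeiouy]les$", v)) |
        (grepl("[^aeiouy]ed$", v) & !grepl("[td]ed$", v))
      groups <- groups - as.integer(silent & groups > 1L)
      out[todo[alpha]] <- pmax(1L, groups)
    }
  }
  out
}

# Inflection-stripping transforms for easy-list lookup, tried in order.
.inflection_rules <- list(
  c("([a-z])\\1(ed|ing)$", "\\1"),  # stopped/running -> stop/run
  c("ies$", "y"),
  c("ied$", "y"),
  c("ing$", "e"),                   # baking -> bake
  c("ing$", ""),
  c("ed$", "e"),                    # baked -> bake
  c("ed$", ""),
  c("es$", ""),
  c("s$", "")
)

#' Classify words as hard (absent from the easy-word list)
#'
#' Lookup is case-insensitive; possessive markers are removed and regular
#' inflections (-s, -es, -ied/-ies, -ed, -ing, with consonant undoubling and
#' final-e restoration) are stripped before membership is decided. Tokens
#' with no alphabetic character (numerals) are never counted as hard.
#'
#' @param words Character vector of word tokens.
#' @param easy_list Character vector from [load_easy_words()].
#' @return Logical vector, `TRUE` where the word is hard.
#' @export
is_hard_word <- function(words, easy_list = load_easy_words()) {
  if (length(easy_list) == 0L) {
    stop_pemread("easy-word list is empty", "pemread_config_error")
  }
  if (length(words) == 0L) return(logical(0))
  w <- tolower(words)
  w <- sub("'s$|s'$", "", w)
  w <- gsub("'", "", w, fixed = TRUE)
  easy <- w %in% easy_list
  for (rule in .inflection_rules) {
    rem <- !easy
    if (!any(rem)) break
    cand <- sub(rule[[1]], rule[[2]], w[rem])
    easy[rem] <- cand %in% easy_list
  }
  # numerals and other non-alphabetic tokens are treated as familiar
  easy[!grepl("[a-z]", w)] <- TRUE
  !easy
}

#' Construct surface metrics from raw counts
#'
#' Builds the `surface_metrics` container holding every count and average
#' the readability formulas use. Usually produced by
#' [compute_surface_metrics()]; exported so that known counts (e.g. from a
#' hand calculation) can be fed to the formulas directly.
#'
#' @param n_sentences,n_words,n_syllables,n_polysyllables,n_hard_words
#'   Non-negative counts; `n_sentences` and `n_words` must be >= 1 and
#'   `n_syllables >= n_words`.
#' @return Object of class `surface_metrics`.
#' @export
surface_metrics <- function(n_sentences, n_words, n_syllables,
                            n_polysyllables = 0L, n_hard_words = 0L) {
  stopifnot(n_sentences >= 1, n_words >= 1, n_syllables >= n_words,
            n_polysyllables >= 0, n_polysyllables <= n_words,
            n_hard_words >= 0, n_hard_words <= n_words)
  structure(list(
    n_sentences = as.integer(n_sentences),
    n_words = as.integer(n_words),
    n_syllables = as.integer(n_syllables),
    n_polysyllables = as.integer(n_polysyllables),
    n_hard_words = as.integer(n_hard_words),
    avg_words_per_sentence = n_words / n_sentences,
    avg_syllables_per_word = n_syllables / n_words,
    polysyllables_per_sentence = n_polysyllables / n_sentences
  ), class = "surface_metrics")
}

#' @export
print.surface_metrics <- function(x, ...) {
  cat("Surface metrics:",
      x$n_sentences, "sentences,",
      x$n_words, "words,",
      x$n_syllables, "syllables\n")
  cat(sprintf("  words/sentence %.2f, syllables/word %.3f, polysyllables %d, hard words %d\n",
              x$avg_words_per_sentence, x$avg_syllables_per_word,
              x$n_polysyllables, x$n_hard_words))
  invisible(x)
}

#' Compute surface metrics for a document
#'
#' Segments cleaned text into sentences, tokenizes each sentence, counts
#' syllables, polysyllables (>= 3 syllables) and hard words, and derives the
#' per-sentence / per-word averages used by all four readability formulas.
#'
#' @param text Cleaned non-empty document text (see [clean_text()]).
#' @param easy_list Easy-word list, see [load_easy_words()].
#' @param lexicon Syllable lexicon, see [load_syllable_lexicon()].
#' @return Object of class `surface_metrics`.
#' @export
compute_surface_metrics <- function(text,
                                    easy_list = load_easy_words(),
                                    lexicon = load_syllable_lexicon()) {
  sentences <- segment_sentences(text)
  toks <- strsplit(sentences, "[[:space:]]+")
  flat <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", unlist(toks, use.names = FALSE))
  lens <- vapply(toks, length, integer(1))
  keep <- nzchar(flat)
  # per-sentence word counts after dropping punctuation-only tokens
  sent_id <- rep.int(seq_along(lens), lens)[keep]
  words <- flat[keep]
  if (length(words) == 0L) {
    stop_pemread("document has no words", "pemread_empty_document")
  }
  n_sent <- length(unique(sent_id))
  syl <- count_syllables(words, lexicon)
  surface_metrics(
    n_sentences = n_sent,
    n_words = length(words),
    n_syllables = sum(syl),
    n_polysyllables = sum(syl >= 3L),
    n_hard_words = sum(is_hard_word(words, easy_list))
  )
}
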