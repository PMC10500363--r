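# Seeded generator for corpora with known surface statistics. The point is
# a test instrument, not a language model: words are pseudo-words built from
# consonant-vowel units so the intended syllable count and the counted one
# agree by construction, and hard/easy status is controlled exactly.

# Consonant-vowel-consonant units; concatenations never create adjacent
# vowel groups or silent-e endings, so each unit contributes exactly one
# counted syllable, and no concatenation collides with the easy list.
.hard_units <- c("zab", "zib", "zob", "zub", "vax", "vix", "vox", "gak",
                 "gok", "lun", "mun", "pov", "tup", "dax", "fip", "nid",
                 "kog", "rab", "sul", "wub")

#' Distribution specification for the corpus generator
#'
#' A discretized gamma spec: draws come from a gamma distribution with the
#' given mean and standard deviation, rounded to integers and clamped below
#' at `min`. `sd = 0` gives the constant `round(mean)` (degenerate configs
#' used for closed-form checks).
#'
#' @param mean Target mean (> 0).
#' @param sd Standard deviation (>= 0).
#' @param min Lower clamp (default 1).
#' @return Object of class `dist_spec`.
#' @export
dist_spec <- function(mean, sd = 0, min = 1L) {
  stopifnot(is.numeric(mean), mean > 0, is.numeric(sd), sd >= 0, min >= 1)
  structure(list(mean = mean, sd = sd, min = as.integer(min)),
            class = "dist_spec")
}

.draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (n == 0L) return(integer(0))
  if (spec$sd <= 0) {
    x <- rep.int(as.integer(round(spec$mean)), n)
  } else {
    shape <- spec$mean^2 / spec$sd^2
    rate <- spec$mean / spec$sd^2
    x <- as.integer(round(stats::rgamma(n, shape = shape, rate = rate)))
  }
  pmax(spec$min, x)
}

#' Default source-by-topic cell layout
#'
#' Four source categories crossed with five topics in proportions echoing a
#' realistic crawled PEM collection (pregnancy-heavy, mostly educational and
#' nonprofit sources), scaled to about 150 documents for fast tests.
#'
#' @return Data frame with columns `source_category`, `topic`, `n`.
#' @export
default_cells <- function() {
  counts <- rbind(
    pregnancy       = c(educational = 55, nonprofit = 53, commercial = 3, government = 3),
    general_disease = c(educational = 4,  nonprofit = 1,  commercial = 6, government = 3),
    procedure       = c(educational = 4,  nonprofit = 2,  commercial = 2, government = 1),
    menstruation    = c(educational = 2,  nonprofit = 1,  commercial = 2, government = 1),
    cancer          = c(educational = 1,  nonprofit = 1,  commercial = 3, government = 1)
  )
  data.frame(
    source_category = rep(colnames(counts), each = nrow(counts)),
    topic = rep(rownames(counts), times = ncol(counts)),
    n = as.vector(counts),
    stringsAsFactors = FALSE
  )
}

.source_levels <- c("government", "commercial", "nonprofit", "educational")
.topic_levels <- c("pregnancy", "general_disease", "procedure",
                   "menstruation", "cancer")

#' Generator configuration
#'
#' Bundles every knob of the synthetic corpus: the seed, the source-by-topic
#' cell layout, sentence- and word-count distributions, the probability
#' vector over per-word syllable counts 1..5, the hard-word rate, and
#' optional per-category complexity shifts.
#'
#' @param seed Integer RNG seed.
#' @param cells Data frame (`source_category`, `topic`, `n`); defaults to
#'   [default_cells()].
#' @param sentences_per_doc,words_per_sentence [dist_spec()] objects.
#' @param syllable_distribution Probabilities over syllable counts 1..5
#'   (must sum to 1).
#' @param hard_word_rate Probability that a word is off the easy list.
#' @param per_cell_shifts Optional named list: category label (a source or
#'   topic) -> list with `wps` (additive shift to the words-per-sentence
#'   mean) and/or `poly` (probability mass moved from 1-2-syllable words to
#'   3-syllable words).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             cells = default_cells(),
                             sentences_per_doc = dist_spec(12, 4, min = 3),
                             words_per_sentence = dist_spec(15, 4, min = 3),
                             syllable_distribution = c(0.45, 0.30, 0.15, 0.07, 0.03),
                             hard_word_rate = 0.25,
                             per_cell_shifts = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.data.frame(cells) || nrow(cells) == 0L ||
      !all(c("source_category", "topic", "n") %in% names(cells))) {
    stop_pemread("cells must be a non-empty data frame with source_category, topic, n",
                 "pemread_config_error")
  }
  if (!all(cells$source_category %in% .source_levels)) {
    stop_pemread("unknown source category in cells", "pemread_config_error")
  }
  if (!all(cells$topic %in% .topic_levels)) {
    stop_pemread("unknown topic in cells", "pemread_config_error")
  }
  stopifnot(all(cells$n >= 0))
  if (length(syllable_distribution) != 5L ||
      any(syllable_distribution < 0) ||
      abs(sum(syllable_distribution) - 1) > 1e-9) {
    stop_pemread("syllable_distribution must be 5 probabilities summing to 1",
                 "pemread_config_error")
  }
  stopifnot(hard_word_rate >= 0, hard_word_rate <= 1)
  structure(list(
    seed = as.integer(seed),
    cells = cells,
    sentences_per_doc = sentences_per_doc,
    words_per_sentence = words_per_sentence,
    syllable_distribution = syllable_distribution,
    hard_word_rate = hard_word_rate,
    per_cell_shifts = per_cell_shifts
  ), class = "generator_config")
}

# index the easy list by counted syllables (cached per easy list content)
.easy_index <- function(easy_list, lexicon) {
  key <- paste0("easy_index_", length(easy_list))
  cached <- .pemread_cache[[key]]
  if (!is.null(cached) && identical(cached$words, easy_list)) return(cached$index)
  syl <- count_syllables(easy_list, lexicon)
  index <- split(easy_list, syl)
  .pemread_cache[[key]] <- list(words = easy_list, index = index)
  index
}

#' Generate pseudo-words with a known syllable count and hardness
#'
#' Easy words are sampled from the packaged easy-word list among entries
#' whose counted syllables equal the request; hard words are built by
#' concatenating consonant-vowel-consonant units absent from the easy list,
#' one unit per syllable. Either way [count_syllables()] returns exactly the
#' requested count. If the easy list has no word of the requested length the
#' word is built from units (and will count as hard); with the packaged list
#' this only happens for 5-syllable requests.
#'
#' @param n_syllables Integer vector of requested syllable counts (>= 1).
#' @param hard Logical vector: build the word off the easy list.
#' @param easy_list,lexicon See [load_easy_words()].
#' @return Character vector of words. Uses the current RNG stream.
#' @export
generate_word <- function(n_syllables, hard,
                          easy_list = load_easy_words(),
                          lexicon = load_syllable_lexicon()) {
  stopifnot(all(n_syllables >= 1L), length(hard) == length(n_syllables))
  k <- length(n_syllables)
  out <- character(k)
  index <- .easy_index(easy_list, lexicon)
  pool_ok <- !hard & as.character(n_syllables) %in% names(index)
  for (s in unique(n_syllables[pool_ok])) {
    sel <- pool_ok & n_syllables == s
    pool <- index[[as.character(s)]]
    out[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  need_units <- !pool_ok
  if (any(need_units)) {
    for (s in unique(n_syllables[need_units])) {
      sel <- need_units & n_syllables == s
      m <- sum(sel)
      units <- matrix(.hard_units[sample.int(length(.hard_units), m * s,
                                             replace = TRUE)], nrow = s)
      out[sel] <- apply(units, 2, paste, collapse = "")
    }
  }
  out
}

# realized per-cell parameters after applying per_cell_shifts
.cell_params <- function(config, source, topic) {
  wps <- config$words_per_sentence
  sylp <- config$syllable_distribution
  shifts <- config$per_cell_shifts
  if (!is.null(shifts)) {
    for (lab in intersect(names(shifts), c(source, topic))) {
      sh <- shifts[[lab]]
      if (!is.null(sh$wps)) wps <- dist_spec(wps$mean + sh$wps, wps$sd, wps$min)
      if (!is.null(sh$poly) && sh$poly > 0) {
        # move probability mass from 1-2-syllable words onto 3 syllables
        take <- min(sh$poly, sylp[1] + sylp[2])
        t1 <- min(take * sylp[1] / (sylp[1] + sylp[2]), sylp[1])
        t2 <- take - t1
        sylp <- sylp + c(-t1, -t2, take, 0, 0)
      }
    }
  }
  list(wps = wps, sylp = sylp)
}

#' Generate one synthetic document
#'
#' Draws a sentence count, per-sentence word counts, per-word syllable
#' counts and hard-word flags from the configured distributions (with the
#' cell's shifts applied) and renders the document as capitalized
#' period-terminated sentences. Uses the current RNG stream.
#'
#' @param config A [generator_config()].
#' @param source_category,topic Cell labels for the document metadata.
#' @param doc_id Document identifier.
#' @param easy_list,lexicon See [load_easy_words()].
#' @return Object of class `pem_document`.
#' @export
generate_document <- function(config, source_category, topic,
                              doc_id = "doc1",
                              easy_list = load_easy_words(),
                              lexicon = load_syllable_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  par <- .cell_params(config, source_category, topic)
  n_sent <- .draw_dist(config$sentences_per_doc, 1L)
  wps <- .draw_dist(par$wps, n_sent)
  n_words <- sum(wps)
  syl <- sample.int(5L, n_words, replace = TRUE, prob = par$sylp)
  hard <- stats::runif(n_words) < config$hard_word_rate
  words <- generate_word(syl, hard, easy_list, lexicon)
  sent_id <- rep.int(seq_len(n_sent), wps)
  sentences <- vapply(split(words, sent_id), paste, character(1), collapse = " ")
  substr(sentences, 1L, 1L) <- toupper(substr(sentences, 1L, 1L))
  text <- paste0(paste0(sentences, "."), collapse = " ")
  structure(list(
    doc_id = doc_id,
    raw_text = text,
    source_category = source_category,
    topics = topic,
    primary_topic = topic
  ), class = "pem_document")
}

#' Generate a full synthetic corpus
#'
#' One document per requested cell slot, fully reproducible from the config
#' seed (the caller's RNG state is saved and restored).
#'
#' @param config A [generator_config()].
#' @param easy_list,lexicon See [load_easy_words()].
#' @return Object of class `pem_corpus`: list with `documents` (list of
#'   `pem_document`) and `metadata` (data frame).
#' @export
generate_corpus <- function(config,
                            easy_list = load_easy_words(),
                            lexicon = load_syllable_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  cells <- config$cells[config$cells$n > 0L, , drop = FALSE]
  if (nrow(cells) == 0L) {
    stop_pemread("generator config has no documents to generate",
                 "pemread_config_error")
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  total <- sum(cells$n)
  width <- max(4L, nchar(as.character(total)))
  docs <- vector("list", total)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (j in seq_len(cells$n[ci])) {
      idx <- idx + 1L
      docs[[idx]] <- generate_document(
        config, cells$source_category[ci], cells$topic[ci],
        doc_id = sprintf("doc%0*d", width, idx),
        easy_list = easy_list, lexicon = lexicon)
    }
  }
  pem_corpus(docs)
}

#' Construct a corpus object from a list of documents
#'
#' @param documents List of `pem_document` objects with unique `doc_id`s.
#' @return Object of class `pem_corpus`.
#' @export
pem_corpus <- function(documents) {
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop_pemread("duplicate doc_id in corpus", "pemread_input_error")
  }
  meta <- data.frame(
    doc_id = ids,
    source_category = vapply(documents, `[[`, character(1), "source_category"),
    topics = vapply(documents, function(d) paste(d$topics, collapse = ";"),
                    character(1)),
    primary_topic = vapply(documents, `[[`, character(1), "primary_topic"),
    stringsAsFactors = FALSE
  )
  structure(list(documents = documents, metadata = meta),
            class = "pem_corpus")
}

#' @export
print.pem_corpus <- function(x, ...) {
  cat("PEM corpus:", length(x$documents), "documents\n")
  print(table(source = x$metadata$source_category,
              topic = x$metadata$primary_topic))
  invisible(x)
}

#' @export
length.pem_corpus <- function(x) length(x$documents)
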