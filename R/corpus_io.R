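#' Write a corpus to a directory
#'
#' Emits `metadata.csv` (`doc_id,source_category,topics,primary_topic`,
#' topics semicolon-separated) plus one UTF-8 `<doc_id>.txt` per document.
#'
#' @param corpus A `pem_corpus`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "pem_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (doc in corpus$documents) {
    writeLines(doc$raw_text, file.path(dir, paste0(doc$doc_id, ".txt")),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Load a corpus from a directory
#'
#' Expects the layout written by [write_corpus()]: a `metadata.csv` with
#' columns `doc_id,source_category,topics,primary_topic` and one `.txt`
#' file per `doc_id`. Document text is normalized with [clean_text()] at
#' load. Duplicate ids, unknown category labels, topic sets not containing
#' the primary topic, and missing text files are reported as errors naming
#' the offending `doc_id`.
#'
#' @param dir Corpus directory.
#' @return Object of class `pem_corpus`.
#' @export
load_corpus <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop_pemread(paste0("no metadata.csv in ", dir), "pemread_input_error")
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("doc_id", "source_category", "topics", "primary_topic")
  if (!all(need %in% names(meta))) {
    stop_pemread("metadata.csv must have columns doc_id, source_category, topics, primary_topic",
                 "pemread_input_error")
  }
  dup <- meta$doc_id[duplicated(meta$doc_id)]
  if (length(dup)) {
    stop_pemread(paste0("duplicate doc_id: ", paste(unique(dup), collapse = ", ")),
                 "pemread_input_error")
  }
  docs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$doc_id[i]
    src <- meta$source_category[i]
    topics <- strsplit(meta$topics[i], ";", fixed = TRUE)[[1]]
    topics <- trimws(topics)
    primary <- meta$primary_topic[i]
    if (!src %in% .source_levels) {
      stop_pemread(paste0("doc ", id, ": unknown source category '", src, "'"),
                   "pemread_input_error")
    }
    if (length(topics) == 0L || !all(topics %in% .topic_levels)) {
      stop_pemread(paste0("doc ", id, ": invalid topic labels"),
                   "pemread_input_error")
    }
    if (!primary %in% topics) {
      stop_pemread(paste0("doc ", id, ": primary_topic not among topics"),
                   "pemread_input_error")
    }
    txt_path <- file.path(dir, paste0(id, ".txt"))
    if (!file.exists(txt_path)) {
      stop_pemread(paste0("doc ", id, ": text file not found (", txt_path, ")"),
                   "pemread_input_error")
    }
    raw <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    docs[[i]] <- structure(list(
      doc_id = id,
      raw_text = clean_text(raw),
      source_category = src,
      topics = topics,
      primary_topic = primary
    ), class = "pem_document")
  }
  pem_corpus(docs)
}

#' Partition documents by the minimum-word screening rule
#'
#' Mirrors the screening step in which documents too short for Gunning fog
#' scoring (under `min_words` words) are removed before any analysis; they
#' are still reported in the pipeline counts.
#'
#' @param corpus A `pem_corpus`.
#' @param min_words Minimum word count (default 100).
#' @return List with `eligible` and `excluded` (`pem_corpus` or `NULL` when
#'   a side is empty) and `n_words` (named per-document counts).
#' @export
apply_length_filter <- function(corpus, min_words = 100L) {
  stopifnot(inherits(corpus, "pem_corpus"))
  n_words <- vapply(corpus$documents, function(doc) {
    toks <- tokenize_words(doc$raw_text)
    length(toks)
  }, integer(1))
  names(n_words) <- corpus$metadata$doc_id
  keep <- n_words >= min_words
  list(
    eligible = if (any(keep)) pem_corpus(corpus$documents[keep]) else NULL,
    excluded = if (any(!keep)) pem_corpus(corpus$documents[!keep]) else NULL,
    n_words = n_words
  )
}
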