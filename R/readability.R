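#' Flesch-Kincaid grade level
#'
#' `0.39 * words/sentence + 11.8 * syllables/word - 15.59`. The value is
#' returned unclamped (it can be negative or exceed 16); clamping to the
#' grade-4..16 scale happens only in [to_grade_category()].
#'
#' @param metrics A `surface_metrics` object.
#' @return Real grade level.
#' @export
fkgl <- function(metrics) {
  stopifnot(inherits(metrics, "surface_metrics"))
  0.39 * metrics$avg_words_per_sentence +
    11.8 * metrics$avg_syllables_per_word - 15.59
}

#' Gunning fog index
#'
#' `0.4 * (words/sentence + 100 * polysyllables/words)`, defined only for
#' documents of at least `min_words` words; shorter documents raise an
#' ineligibility error and are excluded from scoring.
#'
#' @param metrics A `surface_metrics` object.
#' @param min_words Minimum document length in words (default 100).
#' @return Real grade level.
#' @export
gfi <- function(metrics, min_words = 100L) {
  stopifnot(inherits(metrics, "surface_metrics"))
  if (metrics$n_words < min_words) {
    stop_pemread(
      sprintf("document has %d words; GFI requires at least %d",
              metrics$n_words, min_words),
      "pemread_ineligible_document")
  }
  0.4 * (metrics$avg_words_per_sentence +
           100 * metrics$n_polysyllables / metrics$n_words)
}

# nearest perfect square; a count equidistant from two squares takes the lower
.nearest_square_root <- function(x) {
  r <- floor(sqrt(x))
  lo <- r^2
  hi <- (r + 1)^2
  ifelse(x - lo <= hi - x, r, r + 1)
}

#' SMOG grade level
#'
#' With 30 or more sentences the grade is `3 + sqrt(S)` where `S` is the
#' perfect square nearest the polysyllable count (ties resolve to the lower
#' square). With fewer sentences the polysyllable count is scaled to 30
#' sentences (`raw = polysyllables * 30 / sentences`), rounded half-up to an
#' integer, and converted with [smog_raw_to_grade()]. The result is an
#' integer grade clamped to 5..18.
#'
#' @param metrics A `surface_metrics` object.
#' @return Integer grade level in 5..18.
#' @export
smog <- function(metrics) {
  stopifnot(inherits(metrics, "surface_metrics"))
  if (metrics$n_sentences >= 30L) {
    g <- 3 + .nearest_square_root(metrics$n_polysyllables)
    return(as.integer(min(18, max(5, g))))
  }
  raw <- metrics$n_polysyllables * 30 / metrics$n_sentences
  raw <- floor(raw + 0.5)  # half-up, deterministic
  if (raw < 1) return(5L)  # no polysyllables: bottom of the scale
  smog_raw_to_grade(raw)
}

#' Convert a rounded SMOG raw score to a grade level
#'
#' Grade 5 for raw scores 1..6; grade `R` (6..17) for raw scores in
#' `[R^2 - 7R + 13, (R - 2)(R - 3)]`; grade 18 for raw scores >= 211. The
#' intervals tile the integers with no gap or overlap.
#'
#' @param raw Integer raw score(s), >= 1.
#' @return Integer grade level(s) in 5..18.
#' @export
smog_raw_to_grade <- function(raw) {
  if (any(raw < 1)) {
    stop_pemread("SMOG raw score must be >= 1", "pemread_domain_error")
  }
  R <- 6:17
  lower <- c(1, R^2 - 7 * R + 13, 211)
  grades <- c(5L, R, 18L)
  grades[findInterval(raw, lower)]
}

#' Dale-Chall raw score
#'
#' `0.0496 * words/sentence + 15.79 * hard_words/words + 3.6365`, with the
#' 3.6365 constant added unconditionally. Set `classical = TRUE` for the
#' classical New Dale-Chall behaviour, which adds the constant only when
#' hard words exceed 5% of the text.
#'
#' @param metrics A `surface_metrics` object.
#' @param classical Apply the constant conditionally (default `FALSE`).
#' @return Real raw score.
#' @export
dcl_raw <- function(metrics, classical = FALSE) {
  stopifnot(inherits(metrics, "surface_metrics"))
  hard_frac <- metrics$n_hard_words / metrics$n_words
  base <- 0.0496 * metrics$avg_words_per_sentence + 15.79 * hard_frac
  if (classical && hard_frac <= 0.05) base else base + 3.6365
}

#' Convert a Dale-Chall raw score to a grade level
#'
#' Grade 4 below raw 5; the integer part of `2*raw - 5` for raw in \[5, 9);
#' the integer part of `3*raw - 14` for raw in \[9, 10); grade 16 at or above
#' raw 10. The result is clamped to 4..16. (The piecewise map is printed
#' only for raw "between 5 and 8" and "9"; extending the first piece to
#' \[5, 9) keeps the map monotone and gap-free.)
#'
#' @param raw Real raw score(s).
#' @return Integer grade level(s) in 4..16.
#' @export
dcl_raw_to_grade <- function(raw) {
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  g <- ifelse(raw < 5, 4,
       ifelse(raw < 9, trunc(2 * raw - 5),
       ifelse(raw < 10, trunc(3 * raw - 14), 16)))
  as.integer(pmin(16, pmax(4, g)))
}

#' Integerize and clamp a score to the grade-4..16 scale
#'
#' Keeps only the integer part (truncation toward zero) of a real score and
#' clamps it to the 4..16 grade scale shared by all four measures.
#'
#' @param score Real score(s).
#' @return Integer grade(s) in 4..16.
#' @export
to_grade_category <- function(score) {
  stopifnot(is.numeric(score), all(is.finite(score)))
  as.integer(pmin(16, pmax(4, trunc(score))))
}

#' Composite readability score
#'
#' Aggregates the four per-measure grade levels (real-valued FKGL and GFI,
#' integer SMOG and Dale-Chall grades) into one number by mean or median
#' (the median of four values is the mean of the two middle ones).
#'
#' @param grades Numeric vector of the four grade-level values.
#' @param method `"mean"` or `"median"`.
#' @return Real composite score, or `NA` if any grade is missing (document
#'   failed the length filter).
#' @export
composite <- function(grades, method = c("mean", "median")) {
  method <- match.arg(method)
  if (anyNA(grades)) return(NA_real_)
  if (method == "mean") mean(grades) else stats::median(grades)
}

#' Score one document on all four measures
#'
#' @param text Raw or cleaned document text.
#' @param easy_list,lexicon See [load_easy_words()], [load_syllable_lexicon()].
#' @param min_words Minimum length for GFI eligibility (default 100).
#' @param clean Apply [clean_text()] first (default `TRUE`).
#' @return Object of class `readability_scores`: a list with the surface
#'   metrics, `fkgl`, `gfi` (`NA` for short documents), `smog`, `dcl_raw`,
#'   `dcl_grade`, `composite_mean`, `composite_median` and `excluded` flag.
#' @export
score_document <- function(text, easy_list = load_easy_words(),
                           lexicon = load_syllable_lexicon(),
                           min_words = 100L, clean = TRUE) {
  if (clean) text <- clean_text(text)
  m <- compute_surface_metrics(text, easy_list, lexicon)
  f <- fkgl(m)
  g <- if (m$n_words >= min_words) gfi(m, min_words) else NA_real_
  s <- smog(m)
  dr <- dcl_raw(m)
  dg <- dcl_raw_to_grade(dr)
  grades <- c(fkgl = f, gfi = g, smog = s, dcl = dg)
  structure(list(
    metrics = m,
    fkgl = f, gfi = g, smog = s,
    dcl_raw = dr, dcl_grade = dg,
    composite_mean = composite(grades, "mean"),
    composite_median = composite(grades, "median"),
    excluded = m$n_words < min_words
  ), class = "readability_scores")
}

#' @export
print.readability_scores <- function(x, digits = 2, ...) {
  cat("Readability scores (", x$metrics$n_words, " words, ",
      x$metrics$n_sentences, " sentences)\n", sep = "")
  cat(sprintf("  FKGL %.*f | GFI %s | SMOG %d | DCL raw %.*f (grade %d)\n",
              digits, x$fkgl,
              if (is.na(x$gfi)) "NA (short document)" else
                sprintf("%.*f", digits, x$gfi),
              x$smog, digits, x$dcl_raw, x$dcl_grade))
  if (!is.na(x$composite_mean)) {
    cat(sprintf("  composite: mean %.*f, median %.*f\n",
                digits, x$composite_mean, digits, x$composite_median))
  } else {
    cat("  composite: NA (document under the word minimum, excluded)\n")
  }
  invisible(x)
}

#' Score every document in a corpus
#'
#' @param corpus A `pem_corpus` (see [load_corpus()], [generate_corpus()]).
#' @param easy_list,lexicon,min_words As in [score_document()].
#' @return Data frame with one row per document: `doc_id`, `n_words`,
#'   `n_sentences`, `fkgl`, `gfi`, `smog`, `dcl_raw`, `dcl_grade`,
#'   `composite_mean`, `composite_median`, `grade_category` (integer part of
#'   the mean composite, clamped to 4..16) and `excluded_flag`.
#' @export
score_corpus <- function(corpus, easy_list = load_easy_words(),
                         lexicon = load_syllable_lexicon(),
                         min_words = 100L) {
  stopifnot(inherits(corpus, "pem_corpus"))
  rows <- lapply(corpus$documents, function(doc) {
    s <- score_document(doc$raw_text, easy_list, lexicon, min_words,
                        clean = FALSE)
    data.frame(
      doc_id = doc$doc_id,
      n_words = s$metrics$n_words,
      n_sentences = s$metrics$n_sentences,
      fkgl = s$fkgl, gfi = s$gfi, smog = s$smog,
      dcl_raw = s$dcl_raw, dcl_grade = s$dcl_grade,
      composite_mean = s$composite_mean,
      composite_median = s$composite_median,
      grade_category = if (is.na(s$composite_mean)) NA_integer_ else
        to_grade_category(s$composite_mean),
      excluded_flag = s$excluded,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
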