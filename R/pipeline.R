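#' Run the full readability-analysis pipeline
#'
#' Executes the complete flow on a corpus: surface metrics and the four
#' readability measures per document, the minimum-word screening, the
#' composite-grade distribution, inter-measure agreement (Fleiss kappa under
#' the 13-, 3- and 2-category schemes), the Shapiro-Wilk normality gate, the
#' one-sample Wilcoxon test against the recommended eighth-grade level, and
#' Kruskal-Wallis plus Bonferroni-corrected pairwise Mann-Whitney
#' comparisons across source and topic categories.
#'
#' @param corpus A `pem_corpus`.
#' @param easy_list,lexicon See [load_easy_words()], [load_syllable_lexicon()].
#' @param min_words Screening threshold in words (default 100).
#' @param composite Which composite feeds the statistics: `"mean"` (default)
#'   or `"median"`.
#' @param threshold Recommended grade level for the one-sample test
#'   (default 8).
#' @param alpha Significance level for the normality gate and the pairwise
#'   familywise correction (default 0.05).
#' @param verbose Log each stage with document counts (default `FALSE`).
#' @return Object of class `pem_report`; see Details.
#' @details The report holds `n_input_documents`, `n_excluded_short`,
#'   `n_analyzed`, the per-document `scores` table, the composite
#'   `grade_distribution` (count and cumulative percentage per grade), the
#'   per-scheme `agreement` list, `normality`, `threshold_test`, and
#'   `comparisons$source` / `comparisons$topic` (each a main Kruskal-Wallis
#'   effect plus the pairwise table). Degenerate stages (undefined kappa,
#'   constant scores, fewer than two categories) are recorded in `notes`
#'   rather than aborting the run.
#' @export
run_pipeline <- function(corpus,
                         easy_list = load_easy_words(),
                         lexicon = load_syllable_lexicon(),
                         min_words = 100L,
                         composite = c("mean", "median"),
                         threshold = 8,
                         alpha = 0.05,
                         verbose = FALSE) {
  stopifnot(inherits(corpus, "pem_corpus"))
  composite <- match.arg(composite)
  notes <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))

  say("scoring %d documents", length(corpus$documents))
  scores <- score_corpus(corpus, easy_list, lexicon, min_words)
  n_input <- nrow(scores)
  n_excluded <- sum(scores$excluded_flag)
  n_analyzed <- n_input - n_excluded
  say("screening: %d input, %d excluded (<%d words), %d analyzed",
      n_input, n_excluded, min_words, n_analyzed)
  if (n_analyzed < 2L) {
    stop_pemread("fewer than 2 documents survive the length filter",
                 "pemread_pipeline_error")
  }
  analyzed <- scores[!scores$excluded_flag, , drop = FALSE]
  comp_col <- if (composite == "mean") "composite_mean" else "composite_median"
  comp <- analyzed[[comp_col]]

  # composite-grade distribution (count + cumulative %)
  grades <- to_grade_category(comp)
  tab <- table(factor(grades, levels = 4:16))
  dist <- data.frame(
    grade = 4:16,
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / n_analyzed
  )
  dist$cum_n <- cumsum(dist$n)
  dist$cum_pct <- 100 * dist$cum_n / n_analyzed
  dist <- dist[dist$cum_n > 0, , drop = FALSE]  # drop leading empty grades
  rownames(dist) <- NULL

  # inter-measure agreement under the three binning schemes
  say("agreement analysis on %d documents", n_analyzed)
  agreement <- lapply(c(thirteen = "thirteen", three = "three", two = "two"),
    function(sch) {
      ratings <- build_ratings(scores, sch)
      withCallingHandlers(
        fleiss_kappa(ratings),
        pemread_degenerate_agreement = function(w) {
          notes <<- c(notes, sprintf("agreement (%s): %s", sch,
                                     conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
    })

  # normality gate
  normality <- tryCatch(test_normality(comp), pemread_degenerate_sample =
    function(e) {
      notes <<- c(notes, paste("normality:", conditionMessage(e)))
      NULL
    })
  nonnormal <- !is.null(normality) && normality$p.value < alpha
  if (!is.null(normality)) {
    say("Shapiro-Wilk p = %.3g -> %s branch", normality$p.value,
        if (nonnormal) "nonparametric" else "parametric-eligible")
  }

  # one-sample location test against the recommended grade
  threshold_test <- tryCatch(test_above_threshold(comp, threshold),
    pemread_degenerate_sample = function(e) {
      notes <<- c(notes, paste("threshold test:", conditionMessage(e)))
      NULL
    })

  # group comparisons by source and by primary topic
  meta <- corpus$metadata[match(analyzed$doc_id, corpus$metadata$doc_id), ]
  compare_by <- function(labels, what) {
    groups <- split(comp, labels)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) {
      notes <<- c(notes, sprintf("%s comparison skipped: fewer than 2 categories",
                                 what))
      return(NULL)
    }
    if (length(unique(unlist(groups))) == 1L) {
      notes <<- c(notes, sprintf("%s comparison degenerate: all scores identical",
                                 what))
      return(NULL)
    }
    say("%s comparison across %d categories", what, length(groups))
    list(main = compare_groups(groups),
         pairwise = pairwise_compare(groups, alpha = alpha))
  }
  comparisons <- list(
    source = compare_by(meta$source_category, "source"),
    topic = compare_by(meta$primary_topic, "topic")
  )

  structure(list(
    n_input_documents = n_input,
    n_excluded_short = n_excluded,
    n_analyzed = n_analyzed,
    min_words = min_words,
    composite = composite,
    scores = scores,
    grade_distribution = dist,
    agreement = agreement,
    normality = normality,
    nonnormal = nonnormal,
    threshold = threshold,
    threshold_test = threshold_test,
    comparisons = comparisons,
    alpha = alpha,
    notes = notes
  ), class = "pem_report")
}

#' @export
print.pem_report <- function(x, ...) {
  cat("PEM readability report\n")
  cat(sprintf("  documents: %d input, %d excluded (<%d words), %d analyzed\n",
              x$n_input_documents, x$n_excluded_short, x$min_words,
              x$n_analyzed))
  comp <- x$scores[[if (x$composite == "mean") "composite_mean" else
                      "composite_median"]]
  comp <- comp[!x$scores$excluded_flag]
  cat(sprintf("  composite (%s of 4 measures): median grade %.2f\n",
              x$composite, stats::median(comp)))
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    cat(sprintf("  agreement (%s categories): kappa = %s%s\n", nm,
                if (is.na(a$kappa)) "undefined" else
                  format(a$kappa, digits = 3),
                if (is.na(a$kappa)) "" else paste0(" (", a$interpretation, ")")))
  }
  if (!is.null(x$threshold_test)) {
    cat(sprintf("  above grade %g? one-sided Wilcoxon p = %.3g\n",
                x$threshold, x$threshold_test$p.value))
  }
  for (what in c("source", "topic")) {
    cmp <- x$comparisons[[what]]
    if (!is.null(cmp)) {
      cat(sprintf("  %s main effect: Kruskal-Wallis H = %.2f, p = %.3g\n",
                  what, cmp$main$statistic, cmp$main$p.value))
    }
  }
  if (length(x$notes)) {
    cat("  notes:\n")
    for (n in x$notes) cat("   -", n, "\n")
  }
  invisible(x)
}

#' @export
summary.pem_report <- function(object, ...) {
  print(object)
  cat("\nGrade distribution (composite):\n")
  print(object$grade_distribution, row.names = FALSE)
  for (what in c("source", "topic")) {
    cmp <- object$comparisons[[what]]
    if (!is.null(cmp)) {
      cat(sprintf("\nPairwise Mann-Whitney (%s categories, threshold %.4g):\n",
                  what, cmp$pairwise$adjusted_alpha[1]))
      print(cmp$pairwise, row.names = FALSE, digits = 4)
    }
  }
  invisible(object)
}

#' Write all report artifacts to a directory
#'
#' Emits `scores.csv` (per-document measures), `grade_distribution.csv`,
#' `agreement.json` (one `{scheme, n_items, kappa, interpretation}` entry
#' per binning scheme), `comparison_source.csv` / `comparison_topic.csv`
#' (pairwise tables), and `report.json` with the headline numbers.
#'
#' @param report A `pem_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pem_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$grade_distribution,
                   file.path(dir, "grade_distribution.csv"), row.names = FALSE)
  agree <- lapply(names(report$agreement), function(nm) {
    a <- report$agreement[[nm]]
    list(scheme = nm, n_items = a$n_items, kappa = a$kappa,
         interpretation = a$interpretation)
  })
  jsonlite::write_json(agree, file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (what in c("source", "topic")) {
    cmp <- report$comparisons[[what]]
    if (!is.null(cmp)) {
      utils::write.csv(cmp$pairwise,
                       file.path(dir, paste0("comparison_", what, ".csv")),
                       row.names = FALSE)
    }
  }
  comp <- report$scores[[if (report$composite == "mean") "composite_mean"
                         else "composite_median"]]
  comp <- comp[!report$scores$excluded_flag]
  headline <- list(
    n_input_documents = report$n_input_documents,
    n_excluded_short = report$n_excluded_short,
    n_analyzed = report$n_analyzed,
    composite = report$composite,
    median_composite = stats::median(comp),
    shapiro_p = if (is.null(report$normality)) NULL else
      report$normality$p.value,
    wilcoxon_above_threshold_p = if (is.null(report$threshold_test)) NULL
      else report$threshold_test$p.value,
    kruskal_wallis = list(
      source = if (is.null(report$comparisons$source)) NULL else
        list(H = report$comparisons$source$main$statistic,
             p = report$comparisons$source$main$p.value),
      topic = if (is.null(report$comparisons$topic)) NULL else
        list(H = report$comparisons$topic$main$statistic,
             p = report$comparisons$topic$main$p.value)
    ),
    notes = report$notes
  )
  jsonlite::write_json(headline, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
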