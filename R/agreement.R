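#' Grade-category binning schemes
#'
#' Maps integer grade levels (4..16, from [to_grade_category()]) to the
#' categorical scales used for the agreement analysis:
#' `"thirteen"` keeps one category per grade (4..16); `"three"` uses
#' below-sixth / sixth-to-eighth / above-eighth (`"<6"`, `"6-8"`, `">8"`);
#' `"two"` splits at the recommended eighth grade (`"<=8"`, `">8"`).
#'
#' @param grades Integer vector of grade levels in 4..16.
#' @param scheme One of `"thirteen"`, `"three"`, `"two"`.
#' @return Factor with the scheme's full category set as levels.
#' @export
bin_scores <- function(grades, scheme = c("thirteen", "three", "two")) {
  if (!is.character(scheme) || !all(scheme %in% c("thirteen", "three", "two"))) {
    stop_pemread("unknown binning scheme", "pemread_config_error")
  }
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(grades), all(is.finite(grades)),
            all(grades == trunc(grades)), all(grades >= 4 & grades <= 16))
  switch(scheme,
    thirteen = factor(as.character(grades), levels = as.character(4:16)),
    three = factor(ifelse(grades < 6, "<6", ifelse(grades <= 8, "6-8", ">8")),
                   levels = c("<6", "6-8", ">8")),
    two = factor(ifelse(grades <= 8, "<=8", ">8"), levels = c("<=8", ">8"))
  )
}

#' Build the documents-by-measures ratings matrix
#'
#' Integerizes each measure's grade (FKGL, GFI, SMOG, Dale-Chall) with
#' [to_grade_category()] and bins it under the requested scheme. Documents
#' excluded by the length filter are dropped listwise.
#'
#' @param scores Data frame from [score_corpus()].
#' @param scheme Binning scheme, see [bin_scores()].
#' @return Object of class `ratings_matrix`: a character matrix (items x
#'   raters) with a `categories` attribute carrying the declared level set.
#' @export
build_ratings <- function(scores, scheme = c("thirteen", "three", "two")) {
  scheme <- match.arg(scheme)
  keep <- !scores$excluded_flag
  scores <- scores[keep, , drop = FALSE]
  if (nrow(scores) < 2L) {
    stop_pemread("need at least 2 analyzed documents for agreement",
                 "pemread_input_error")
  }
  measures <- cbind(
    fkgl = to_grade_category(scores$fkgl),
    gfi = to_grade_category(scores$gfi),
    smog = to_grade_category(scores$smog),
    dcl = to_grade_category(scores$dcl_grade)
  )
  binned <- apply(measures, 2, function(col) as.character(bin_scores(col, scheme)))
  binned <- matrix(binned, nrow = nrow(scores),
                   dimnames = list(scores$doc_id, colnames(measures)))
  structure(binned, class = c("ratings_matrix", class(binned)),
            categories = levels(bin_scores(4L, scheme)), scheme = scheme)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n >= 2` raters assigning each of `N >= 2`
#' items to one of `k` categories: `kappa = (Pbar - Pe) / (1 - Pe)` with
#' per-item observed agreement and chance agreement computed from the
#' category marginals. When every rating falls in a single category the
#' chance agreement is 1 and kappa is undefined; a degenerate-agreement
#' warning is raised and `NA` returned.
#'
#' @param ratings Items-by-raters matrix (character/factor/integer), e.g.
#'   from [build_ratings()].
#' @param categories Optional declared category set; defaults to the
#'   matrix's `categories` attribute or the observed values. Unused declared
#'   categories have zero marginal probability and do not change kappa.
#' @return Object of class `agreement_result`: list with `kappa`, `n_items`,
#'   `n_raters`, `n_categories`, `interpretation`.
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  x <- as.matrix(ratings)
  N <- nrow(x)
  n <- ncol(x)
  if (N < 2L || n < 2L) {
    stop_pemread("Fleiss kappa needs >= 2 items and >= 2 raters",
                 "pemread_input_error")
  }
  if (anyNA(x)) stop_pemread("ratings matrix has missing cells",
                             "pemread_input_error")
  if (is.null(categories)) categories <- attr(ratings, "categories")
  if (is.null(categories)) categories <- sort(unique(as.vector(x)))
  f <- matrix(match(as.vector(x), categories), nrow = N)
  if (anyNA(f)) stop_pemread("rating outside the declared category set",
                             "pemread_input_error")
  k <- length(categories)
  nij <- vapply(seq_len(k), function(j) rowSums(f == j), numeric(N))
  nij <- matrix(nij, nrow = N)
  P_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(nij) / (N * n)
  Pe <- sum(p_j^2)
  if (1 - Pe < 1e-12) {
    warn_pemread("all ratings fall in one category; kappa is undefined",
                 "pemread_degenerate_agreement")
    kap <- NA_real_
  } else {
    kap <- (Pbar - Pe) / (1 - Pe)
  }
  structure(list(
    kappa = kap,
    n_items = N, n_raters = n, n_categories = k,
    interpretation = if (is.na(kap)) NA_character_ else interpret_kappa(kap)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa: %s  (%d items, %d raters, %d categories)\n",
              if (is.na(x$kappa)) "undefined (degenerate)" else
                format(x$kappa, digits = 4),
              x$n_items, x$n_raters, x$n_categories))
  if (!is.na(x$kappa)) cat("  interpretation:", x$interpretation, "\n")
  invisible(x)
}

#' Interpret a kappa value on the conventional agreement bands
#'
#' Negative values indicate poor agreement; then slight (0.00-0.20), fair
#' (0.21-0.40), moderate (0.41-0.60), substantial (0.61-0.80) and almost
#' perfect to perfect (0.81-1.00). The published band table is stated to two
#' decimals, so kappa is rounded to two decimals before lookup (values in
#' the printed gaps, e.g. 0.205, land via rounding).
#'
#' @param kappa Numeric value(s) in \[-1, 1\].
#' @return Character band label(s).
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(is.numeric(kappa))
  if (any(!is.finite(kappa)) || any(kappa < -1 - 1e-9) || any(kappa > 1 + 1e-9)) {
    stop_pemread("kappa must lie in [-1, 1]", "pemread_domain_error")
  }
  k2 <- round(kappa, 2)
  bands <- c("poor", "slight", "fair", "moderate", "substantial",
             "almost perfect to perfect")
  idx <- findInterval(k2, c(-1, 0, 0.205, 0.405, 0.605, 0.805))
  bands[idx]
}
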