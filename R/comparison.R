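#' Shapiro-Wilk normality check
#'
#' Gate for the nonparametric battery: when p < alpha the composite scores
#' are treated as non-normal and rank-based tests are used downstream.
#' `stats::shapiro.test()` accepts at most 5000 values; larger samples are
#' tested on a deterministic subsample (first 5000 after sorting by value
#' rank order would bias, so a fixed-stride thinning of the original order
#' is used).
#'
#' @param values Numeric vector, 3 <= length, not all identical.
#' @return `htest` object with statistic `W` and `p.value`.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop_pemread("need at least 3 values for the normality test",
                 "pemread_input_error")
  }
  if (length(unique(values)) == 1L) {
    stop_pemread("all values identical; normality test is degenerate",
                 "pemread_degenerate_sample")
  }
  if (length(values) > 5000L) {
    idx <- round(seq(1L, length(values), length.out = 5000L))
    values <- values[idx]
  }
  stats::shapiro.test(values)
}

#' One-sample Wilcoxon signed-rank test against a grade threshold
#'
#' Tests whether scores exceed a recommended reading level (default: eighth
#' grade), one-sided (`alternative = "greater"`). Values equal to the
#' threshold are dropped (the signed-rank zero-handling convention); exact
#' p-values are used for small tie-free samples, the normal approximation
#' otherwise.
#'
#' @param values Numeric vector of composite scores.
#' @param threshold Grade-level null location (default 8).
#' @return `htest` object (statistic `V`, one-sided `p.value`).
#' @export
test_above_threshold <- function(values, threshold = 8) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop_pemread("no values to test", "pemread_input_error")
  }
  if (all(values == threshold)) {
    stop_pemread("all values equal the threshold; no informative observations",
                 "pemread_degenerate_sample")
  }
  suppressWarnings(
    stats::wilcox.test(values, mu = threshold, alternative = "greater")
  )
}

#' Kruskal-Wallis main-effect comparison across categories
#'
#' Rank-based test (with tie correction) that at least one category's
#' composite-score distribution differs; p-value from the chi-square
#' approximation with `g - 1` degrees of freedom.
#'
#' @param values_by_group Named list mapping category label to a numeric
#'   vector of composite scores (>= 2 groups, each non-empty).
#' @return List with `statistic` (H), `df`, `p.value` and `medians`
#'   (named per-group medians).
#' @export
compare_groups <- function(values_by_group) {
  .check_groups(values_by_group)
  values <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep.int(names(values_by_group),
                      lengths(values_by_group)),
              levels = names(values_by_group))
  kt <- stats::kruskal.test(values, g)
  list(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value,
    medians = vapply(values_by_group, stats::median, numeric(1))
  )
}

.check_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L ||
      is.null(names(values_by_group)) || any(!nzchar(names(values_by_group)))) {
    stop_pemread("need a named list of >= 2 groups", "pemread_input_error")
  }
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  if (any(lengths(values_by_group) == 0L)) {
    stop_pemread("every group needs at least one observation",
                 "pemread_input_error")
  }
  invisible(TRUE)
}

#' Pairwise Mann-Whitney tests with a Bonferroni-adjusted threshold
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every unordered pair
#' of categories. Exact p-values are computed when both groups have at most
#' `exact_max` observations and the pooled data are tie-free; otherwise the
#' tie-corrected normal approximation (with continuity correction) is used.
#' Significance is declared at the Bonferroni-adjusted threshold
#' `alpha / C(g, 2)` (0.05/6 ~ 0.0083 for four groups, 0.05/10 = 0.005 for
#' five), matching the convention of reporting raw p-values against an
#' adjusted cutoff rather than inflating the p-values.
#'
#' @param values_by_group Named list of per-category score vectors.
#' @param alpha Familywise significance level (default 0.05).
#' @param exact Force exact (`TRUE`) or asymptotic (`FALSE`) p-values;
#'   `NULL` (default) picks exact for small tie-free pairs.
#' @param exact_max Largest per-group size for the automatic exact branch.
#' @return Data frame with one row per pair: `category1`, `category2`,
#'   `median1`, `median2`, `n1`, `n2`, `statistic` (U), `p.value`, `method`,
#'   `adjusted_alpha`, `significant`.
#' @export
pairwise_compare <- function(values_by_group, alpha = 0.05, exact = NULL,
                             exact_max = 8L) {
  .check_groups(values_by_group)
  labs <- names(values_by_group)
  pairs <- utils::combn(labs, 2L)
  n_pairs <- ncol(pairs)
  adj <- alpha / n_pairs
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- values_by_group[[pairs[1L, i]]]
    b <- values_by_group[[pairs[2L, i]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    ties <- anyDuplicated(c(a, b)) > 0L
    use_exact <- if (is.null(exact)) {
      length(a) <= exact_max && length(b) <= exact_max && !ties
    } else {
      exact
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)
    )
    data.frame(
      category1 = pairs[1L, i], category2 = pairs[2L, i],
      median1 = stats::median(a), median2 = stats::median(b),
      n1 = length(a), n2 = length(b),
      statistic = unname(wt$statistic),
      p.value = wt$p.value,
      method = if (use_exact && !ties) "exact" else "asymptotic",
      adjusted_alpha = adj,
      significant = wt$p.value < adj,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
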