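# direct-substitution checks use surface_metrics() so counts are exact
sm <- function(n_sent, n_words, aspw = 1, n_poly = 0, n_hard = 0) {
  surface_metrics(n_sent, n_words, round(n_words * aspw), n_poly, n_hard)
}

test_that("FKGL is the printed linear form in words/sentence and syllables/word", {
  expect_equal(fkgl(sm(5, 100, aspw = 2)), 15.81, tolerance = 1e-9)   # awps 20
  expect_equal(fkgl(sm(10, 100, aspw = 1)), 0.11, tolerance = 1e-9)   # awps 10
  # unclamped: can be negative
  expect_lt(fkgl(sm(10, 30, aspw = 1)), 0)
})

test_that("GFI follows the printed form and enforces the 100-word minimum", {
  expect_equal(gfi(sm(10, 100, n_poly = 8)), 7.2, tolerance = 1e-9)
  expect_equal(gfi(sm(20, 200, n_poly = 0)), 4.0, tolerance = 1e-9)
  expect_error(gfi(sm(10, 99)), class = "pemread_ineligible_document")
})

test_that("SMOG uses nearest-perfect-square above 30 sentences, scaling below", {
  expect_identical(smog(sm(30, 600, n_poly = 64)), 11L)  # 64 is a square
  expect_identical(smog(sm(35, 700, n_poly = 30)), 8L)   # nearest square 25
  expect_identical(smog(sm(10, 200, n_poly = 10)), 8L)   # scaled raw 30
  # tie between squares resolves to the lower square: 20 is 4 from 16 and 25
  expect_identical(smog(sm(30, 600, n_poly = 20)), 7L)
  # no polysyllables: bottom of the scale on both branches
  expect_identical(smog(sm(30, 600, n_poly = 0)), 5L)
  expect_identical(smog(sm(5, 100, n_poly = 0)), 5L)
})

test_that("SMOG raw-to-grade mapping reproduces the printed boundaries", {
  expect_identical(smog_raw_to_grade(6), 5L)
  expect_identical(smog_raw_to_grade(12), 6L)   # R = 6 interval is [7, 12]
  expect_identical(smog_raw_to_grade(211), 18L)
  expect_error(smog_raw_to_grade(0), class = "pemread_domain_error")
})

test_that("SMOG intervals tile the integers 1..300 without gap or overlap", {
  grades <- smog_raw_to_grade(1:300)
  expect_true(all(grades %in% 5:18))
  expect_true(all(diff(grades) >= 0))           # non-decreasing
  # interval bounds: upper(R) + 1 == lower(R + 1) for R = 6..16
  R <- 6:17
  lower <- R^2 - 7 * R + 13
  upper <- (R - 2) * (R - 3)
  expect_identical(lower[1], 7)                 # follows [1, 6]
  expect_identical(upper[-length(R)] + 1, lower[-1])
  expect_identical(upper[length(R)] + 1, 211)   # last interval meets [211, Inf)
  for (i in seq_along(R)) {
    expect_true(all(smog_raw_to_grade(lower[i]:upper[i]) == R[i]))
  }
})

test_that("Dale-Chall raw score is the printed form, constant unconditional", {
  expect_equal(dcl_raw(sm(10, 150, n_hard = 20)), # awps 15, 20/100 scaled
               0.0496 * 15 + 15.79 * 20 / 150 + 3.6365, tolerance = 1e-9)
  expect_equal(dcl_raw(sm(10, 100, n_hard = 0)), 4.1325, tolerance = 1e-9)
  expect_equal(dcl_raw(sm(2, 50, n_hard = 25)), 12.7715, tolerance = 1e-9)
  # classical flag: constant only when hard words exceed 5%
  expect_equal(dcl_raw(sm(10, 100, n_hard = 0), classical = TRUE),
               0.496, tolerance = 1e-9)
  expect_equal(dcl_raw(sm(10, 100, n_hard = 20), classical = TRUE),
               dcl_raw(sm(10, 100, n_hard = 20)), tolerance = 1e-9)
})

test_that("Dale-Chall raw-to-grade mapping matches printed pieces and clamps", {
  expect_identical(dcl_raw_to_grade(4.9), 4L)
  expect_identical(dcl_raw_to_grade(6.0), 7L)     # 2*6 - 5
  expect_identical(dcl_raw_to_grade(10.0), 16L)
  expect_identical(dcl_raw_to_grade(9.0), 13L)    # 3*9 - 14
  expect_identical(dcl_raw_to_grade(c(0, 20)), c(4L, 16L))
  # monotone over a fine grid, including the extended (8, 9) piece
  g <- dcl_raw_to_grade(seq(0, 12, by = 0.01))
  expect_true(all(diff(g) >= 0))
})

test_that("grade integerization truncates then clamps to 4..16", {
  expect_identical(to_grade_category(8.9), 8L)
  expect_identical(to_grade_category(0.89), 4L)
  expect_identical(to_grade_category(17.3), 16L)
  expect_identical(to_grade_category(-2), 4L)
  expect_identical(to_grade_category(16.0), 16L)
})

test_that("composite is the mean / median of the four grade values", {
  expect_equal(composite(c(10, 10, 10, 10), "mean"), 10)
  expect_equal(composite(c(8, 10, 12, 14), "median"), 11)
  expect_equal(composite(c(7.2, 9.5, 11, 13), "mean"), 10.175)
  for (g in 4:16) expect_equal(composite(rep(g, 4), "mean"), g)
  expect_true(is.na(composite(c(NA, 9, 11, 13), "mean")))
})

test_that("each formula is monotone in its complexity inputs", {
  awps <- seq(5, 40, by = 5)
  f <- vapply(awps, function(a) fkgl(sm(10, 10 * a)), numeric(1))
  expect_true(all(diff(f) > 0))
  aspw <- seq(1, 2.5, by = 0.25)
  f2 <- vapply(aspw, function(s) fkgl(sm(10, 200, aspw = s)), numeric(1))
  expect_true(all(diff(f2) > 0))
  poly <- seq(0, 100, by = 10)
  g <- vapply(poly, function(p) gfi(sm(10, 200, n_poly = p)), numeric(1))
  expect_true(all(diff(g) > 0))
  hard <- seq(0, 100, by = 10)
  d <- vapply(hard, function(h) dcl_raw(sm(10, 200, n_hard = h)), numeric(1))
  expect_true(all(diff(d) > 0))
  s <- vapply(seq(0, 200, by = 20),
              function(p) smog(sm(20, 400, n_poly = p)), integer(1))
  expect_true(all(diff(s) >= 0))
})

test_that("score_document assembles measures and composites coherently", {
  # 120 easy monosyllabic words in 10 sentences: every measure in closed form
  sent <- paste(rep("the", 12), collapse = " ")
  text <- paste(rep(paste0(sent, "."), 10), collapse = " ")
  s <- score_document(text)
  expect_identical(s$metrics$n_words, 120L)
  expect_equal(s$fkgl, 0.39 * 12 + 11.8 - 15.59, tolerance = 1e-9)
  expect_equal(s$gfi, 0.4 * 12, tolerance = 1e-9)
  expect_identical(s$smog, 5L)
  expect_equal(s$dcl_raw, 0.0496 * 12 + 3.6365, tolerance = 1e-9)
  expect_identical(s$dcl_grade, 4L)
  grades <- c(s$fkgl, s$gfi, s$smog, s$dcl_grade)
  expect_equal(s$composite_mean, mean(grades), tolerance = 1e-12)
  expect_equal(s$composite_median, median(grades), tolerance = 1e-12)
  expect_false(s$excluded)
  # short documents carry NA GFI and composites and the excluded flag
  short <- score_document("The cat sat on the mat. It ran away.")
  expect_true(short$excluded)
  expect_true(is.na(short$gfi))
  expect_true(is.na(short$composite_mean))
})
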