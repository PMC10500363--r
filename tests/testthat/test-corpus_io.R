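make_fixture_dir <- function() {
  dir <- tempfile("corpus")
  dir.create(dir)
  meta <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    source_category = c("government", "nonprofit", "commercial"),
    topics = c("pregnancy", "pregnancy;cancer", "menstruation"),
    primary_topic = c("pregnancy", "cancer", "menstruation"))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  writeLines("Folic acid helps. Take it daily.", file.path(dir, "d1.txt"))
  writeLines("Screening finds cancer early. Ask your doctor.",
             file.path(dir, "d2.txt"))
  writeLines("Cycles vary. This is normal.", file.path(dir, "d3.txt"))
  dir
}

test_that("a corpus round-trips through the on-disk layout", {
  dir <- make_fixture_dir()
  corp <- load_corpus(dir)
  expect_s3_class(corp, "pem_corpus")
  expect_identical(length(corp), 3L)
  expect_identical(corp$documents[[2]]$topics, c("pregnancy", "cancer"))
  expect_identical(corp$documents[[2]]$primary_topic, "cancer")
  expect_identical(corp$metadata$source_category[1], "government")

  dir2 <- tempfile("copy")
  write_corpus(corp, dir2)
  corp2 <- load_corpus(dir2)
  expect_identical(corp2$metadata, corp$metadata)
  expect_identical(corp2$documents[[1]]$raw_text, corp$documents[[1]]$raw_text)
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("corpus validation names the offending document", {
  dir <- make_fixture_dir()
  # missing text file
  file.remove(file.path(dir, "d2.txt"))
  expect_error(load_corpus(dir), "d2", class = "pemread_input_error")
  unlink(dir, recursive = TRUE)

  # duplicate doc_id
  dir <- make_fixture_dir()
  meta <- read.csv(file.path(dir, "metadata.csv"))
  meta$doc_id <- c("d1", "d1", "d3")
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  expect_error(load_corpus(dir), "duplicate", class = "pemread_input_error")
  unlink(dir, recursive = TRUE)

  # label outside the category vocabulary
  dir <- make_fixture_dir()
  meta <- read.csv(file.path(dir, "metadata.csv"))
  meta$source_category[3] <- "personal_blog"
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  expect_error(load_corpus(dir), "d3", class = "pemread_input_error")
  unlink(dir, recursive = TRUE)
})

test_that("the length filter splits exactly at the word minimum", {
  mk <- function(id, n_words) {
    structure(list(doc_id = id,
                   raw_text = paste0(paste(rep("word", n_words),
                                           collapse = " "), "."),
                   source_category = "government",
                   topics = "pregnancy", primary_topic = "pregnancy"),
              class = "pem_document")
  }
  corp <- pem_corpus(list(mk("a", 99), mk("b", 100), mk("c", 101)))
  flt <- apply_length_filter(corp)
  expect_identical(flt$excluded$metadata$doc_id, "a")
  expect_identical(flt$eligible$metadata$doc_id, c("b", "c"))
  expect_identical(unname(flt$n_words), c(99L, 100L, 101L))

  all_long <- pem_corpus(list(mk("a", 150), mk("b", 150)))
  expect_null(apply_length_filter(all_long)$excluded)
})

test_that("scores CSV round-trips at full precision", {
  cfg <- generator_config(seed = 12, cells = flat_cells(2))
  sc <- score_corpus(generate_corpus(cfg))
  path <- tempfile(fileext = ".csv")
  write.csv(sc, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$fkgl, sc$fkgl, tolerance = 1e-12)
  expect_equal(back$composite_mean, sc$composite_mean, tolerance = 1e-12)
  expect_identical(back$doc_id, sc$doc_id)
  unlink(path)
})

test_that("the pipeline report is deterministic and internally consistent", {
  cfg <- generator_config(seed = 5, cells = flat_cells(c(8, 8, 8, 8)))
  corp <- generate_corpus(cfg)
  r1 <- run_pipeline(corp)
  r2 <- run_pipeline(corp)
  r1$normality$data.name <- r2$normality$data.name <- NULL
  r1$threshold_test$data.name <- r2$threshold_test$data.name <- NULL
  expect_equal(r1[names(r1) != "notes"], r2[names(r2) != "notes"])
  expect_identical(r1$n_input_documents,
                   r1$n_excluded_short + r1$n_analyzed)
  expect_identical(sum(r1$grade_distribution$n), r1$n_analyzed)
  expect_true(all(diff(r1$grade_distribution$cum_pct) >= 0))
  expect_equal(tail(r1$grade_distribution$cum_pct, 1), 100, tolerance = 1e-9)
})

test_that("report invariants hold across random corpora", {
  for (seed in seq(100, 149)) {
    cfg <- generator_config(
      seed = seed, cells = flat_cells(sample(3:6, 4, replace = TRUE)),
      sentences_per_doc = dist_spec(10, 3, min = 2),
      words_per_sentence = dist_spec(13, 4, min = 3))
    rep <- tryCatch(run_pipeline(generate_corpus(cfg)),
                    pemread_pipeline_error = function(e) NULL)
    if (is.null(rep)) next
    expect_identical(rep$n_input_documents,
                     rep$n_excluded_short + rep$n_analyzed)
    expect_identical(sum(rep$grade_distribution$n), rep$n_analyzed)
    expect_true(all(diff(rep$grade_distribution$cum_pct) >= -1e-12))
    expect_equal(tail(rep$grade_distribution$cum_pct, 1), 100,
                 tolerance = 1e-9)
    expect_identical(nrow(rep$scores), rep$n_input_documents)
  }
})

test_that("a corpus of identical documents reports degenerate stages", {
  cfg <- degenerate_config(spd = 10, wps = 12, n_docs = 10)
  corp <- generate_corpus(cfg)
  rep <- run_pipeline(corp)
  expect_true(any(grepl("kappa is undefined", rep$notes)))
  expect_true(any(grepl("normality", rep$notes)))
  expect_true(is.na(rep$agreement$two$kappa))
})

test_that("shifted-category corpora produce significant pairwise flags", {
  cfg <- generator_config(
    seed = 9, cells = flat_cells(30),
    sentences_per_doc = dist_spec(11, 1.5, min = 10),
    words_per_sentence = dist_spec(12, 2, min = 10),
    per_cell_shifts = list(commercial = list(wps = 6)))
  rep <- run_pipeline(generate_corpus(cfg))
  pw <- rep$comparisons$source$pairwise
  hit <- pw$category1 == "commercial" | pw$category2 == "commercial"
  expect_true(all(pw$significant[hit]))
  expect_false(any(pw$significant[!hit]))
})

test_that("write_report emits the full artifact set", {
  cfg <- generator_config(seed = 5, cells = flat_cells(8))
  rep <- run_pipeline(generate_corpus(cfg))
  dir <- tempfile("report")
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scores.csv", "grade_distribution.csv", "agreement.json",
      "comparison_source.csv", "report.json")))))
  agree <- jsonlite::read_json(file.path(dir, "agreement.json"))
  expect_length(agree, 3L)
  expect_identical(agree[[1]]$scheme, "thirteen")
  unlink(dir, recursive = TRUE)
})
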