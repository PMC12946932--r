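emb <- make_embedder()

write_table <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("RF2-style description files load with the active filter", {
  path <- tempfile(fileext = ".tsv")
  generate_snomed_fixture(path)
  tab <- load_snomed(path)
  expect_s3_class(tab, "snomed_table")
  expect_true(all(tab$active == "1"))
  expect_equal(nrow(tab), nrow(snomed_fixture_table()) - 1L)  # one inactive row
  row <- tab[tab$conceptId == "366979004", ]
  expect_equal(row$term, "Depressed mood (finding)")

  # minimal two-column dialect
  p2 <- write_table(data.frame(conceptId = "1", term = "Major depression"))
  expect_equal(nrow(load_snomed(p2)), 1L)

  # header-only file
  p3 <- write_table(data.frame(conceptId = character(0), term = character(0)))
  expect_equal(nrow(load_snomed(p3)), 0L)

  p4 <- write_table(data.frame(id = "1", name = "nope"))
  expect_error(load_snomed(p4), "conceptId",
               class = "phqscreen_validation_error")
  expect_error(load_snomed(tempfile()), class = "phqscreen_io_error")
})

test_that("keyword filtering matches whole words, case-insensitively", {
  tab <- structure(data.frame(
    conceptId = c("1", "2", "3", "4"),
    term = c("Moderate major depression", "Severe depression",
             "Fracture of femur", "Pressing pain"),
    stringsAsFactors = FALSE), class = c("snomed_table", "data.frame"))
  hit <- keyword_filter("moderate depression", tab)
  expect_equal(hit$conceptId, c("1", "2"))
  expect_equal(keyword_filter("DEPRESSION", tab)$conceptId, c("1", "2"))
  # word boundaries: "press" must not match "depression" or "pressing"
  expect_equal(nrow(keyword_filter("press", tab)), 0L)
  expect_equal(nrow(keyword_filter("xyzzy", tab)), 0L)
  expect_error(keyword_filter("the of", tab),
               class = "phqscreen_validation_error")
})

test_that("cosine reranking is ordered and deterministic under ties", {
  tab <- snomed_fixture_table()
  cand <- keyword_filter("moderate depression", tab)
  ranked <- rank_candidates("moderate depression", cand, emb)
  expect_true(all(diff(ranked$similarity) <= 1e-12))
  expect_equal(ranked$term[1], "Moderate major depression")

  # identical term -> similarity 1 at rank 1
  r2 <- rank_candidates("Severe major depression",
                        keyword_filter("Severe major depression", tab), emb)
  expect_equal(r2$term[1], "Severe major depression")
  expect_equal(r2$similarity[1], 1, tolerance = 1e-9)

  # equal-similarity ties break by shorter term then conceptId
  dup <- structure(data.frame(
    conceptId = c("9", "5", "7"),
    term = c("mood swings", "mood", "mood "),
    stringsAsFactors = FALSE), class = c("snomed_table", "data.frame"))
  r3 <- rank_candidates("mood", dup, emb)
  expect_equal(r3$conceptId[1:2], c("5", "7"))
})

test_that("attribution resolves the published worked mappings on the fixture", {
  tab <- snomed_fixture_table()
  m1 <- attribute("Depressed mood (finding)", tab, emb)
  expect_s3_class(m1, "snomed_match")
  expect_equal(m1$conceptId, "366979004")
  expect_equal(m1$similarity, 1, tolerance = 1e-9)

  m2 <- attribute("moderate depression", tab, emb)
  expect_equal(m2$conceptId, "370143000")
  expect_equal(m2$term, "Moderate major depression")

  m3 <- attribute("major depression", tab, emb)
  expect_equal(m3$term, "Major depression")

  expect_true(nzchar(m2$message))
  expect_true(all(c("moduleId", "languageCode", "typeId", "caseSignificanceId")
                  %in% names(m2)))

  nm <- attribute("qqq", tab, emb)
  expect_s3_class(nm, "snomed_nomatch")
})

test_that("attribution equals the brute-force oracle on random tables", {
  diag_words <- c("moderate", "severe", "mild", "major", "depression",
                  "anxiety", "mood", "disorder", "fatigue", "panic")
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:20) {
    tab <- random_snomed_table(sample(c(20L, 80L, 200L), 1), seed = rep)
    for (k in 1:5) {
      d <- paste(sample(diag_words, sample(1:3, 1)), collapse = " ")
      want <- oracle_attribute(d, tab, emb)
      got <- attribute(d, tab, emb)
      if (is.null(want)) {
        expect_s3_class(got, "snomed_nomatch")
      } else {
        expect_equal(got$conceptId, want$conceptId,
                     info = sprintf("rep %d '%s'", rep, d))
        expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("rows matching no keyword never change the result", {
  tab <- snomed_fixture_table()
  base <- attribute("moderate depression", tab, emb)
  extra <- rbind(as.data.frame(tab),
                 data.frame(id = "X1", effectiveTime = "20240101", active = "1",
                            moduleId = "m", conceptId = "1111111",
                            languageCode = "en", typeId = "t",
                            term = "Ingrown toenail",
                            caseSignificanceId = "c"))
  class(extra) <- c("snomed_table", "data.frame")
  expect_equal(attribute("moderate depression", extra, emb)$conceptId,
               base$conceptId)
})

test_that("clinician overrides are honoured and feedback is logged", {
  tab <- snomed_fixture_table()
  m <- attribute("moderate depression", tab, emb,
                 overrides = list("moderate depression" = "9000012"))
  expect_equal(m$conceptId, "9000012")
  expect_equal(m$source, "override")

  log <- tempfile(fileext = ".jsonl")
  log_feedback(log, "moderate depression", "9000012")
  log_feedback(log, "severe depression", "9000003")
  lines <- readLines(log)
  expect_length(lines, 2L)
  expect_equal(jsonlite::fromJSON(lines[1])$conceptId, "9000012")
})
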