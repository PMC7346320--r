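make_report <- function(id = "r1") {
  echo_report(id, patient_id = "p1", exam_time = "2018-01-01",
              exam_item = "经胸超声心动图", exam_category = "超声",
              description = c("EF 值 60%", "左房前后径 35mm。"),
              conclusion = c("主动脉瓣钙化", "二尖瓣狭窄"))
}

test_that("report records round-trip through line-delimited JSON", {
  tmp <- withr::local_tempfile(fileext = ".ndjson")
  reports <- list(make_report("r1"), make_report("r2"), make_report("r3"))
  write_reports(reports, tmp)
  back <- read_reports(tmp)
  expect_length(back, 3L)
  expect_equal(back, reports)

  # empty file -> empty list
  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_length(read_reports(empty), 0L)
})

test_that("malformed report records are rejected with the record index", {
  tmp <- withr::local_tempfile()
  writeLines('{"report_id":"a","patient_id":"p","exam_time":"t","exam_item":"i","exam_category":"c","description":[]}',
             tmp, useBytes = TRUE)
  expect_error(read_reports(tmp), "record 1.*conclusion")

  dup <- withr::local_tempfile()
  write_reports(list(make_report("same"), make_report("same")), dup)
  expect_error(read_reports(dup), "duplicate report_id")

  expect_error(echo_report(""), "non-empty")
})

test_that("normalization strips spaces, lowercases ASCII and joins conclusions with a comma", {
  p <- normalize_report(make_report())
  expect_equal(p$text,
               "ef值60%左房前后径35mm。主动脉瓣钙化，二尖瓣狭窄")
  expect_equal(p$n, nchar(p$text))
  # no spaces and no uppercase ASCII survive
  expect_false(grepl("[ \tA-Z]", p$text))

  # empty report -> empty paragraph
  e <- normalize_report(echo_report("e"))
  expect_equal(e$n, 0L)
  expect_equal(nrow(e$offsets), 0L)
})

test_that("offsets tile the paragraph and slice back to the normalized lines", {
  r <- make_report()
  p <- normalize_report(r)
  src <- c(r$description, r$conclusion)
  for (i in seq_len(nrow(p$offsets))) {
    o <- p$offsets[i, ]
    slice <- substr(p$text, o$start + 1L, o$end)
    expect_equal(slice, echoNER:::normalize_line(src[i]))
    # normalization is idempotent on its own output
    expect_equal(echoNER:::normalize_line(slice), slice)
  }
  # intervals are ordered and disjoint
  expect_true(all(diff(p$offsets$start) > 0))
  expect_true(all(p$offsets$start[-1L] >= p$offsets$end[-nrow(p$offsets)]))
})

test_that("offset round-trip holds across a generated corpus", {
  cp <- generate_corpus(generator_config(n_reports = 20L, seed = 5L))
  for (r in cp$reports[1:10]) {
    p <- normalize_report(r)
    src <- c(r$description, r$conclusion)
    expect_equal(nrow(p$offsets), length(src))
    for (i in seq_len(nrow(p$offsets))) {
      o <- p$offsets[i, ]
      expect_equal(substr(p$text, o$start + 1L, o$end),
                   echoNER:::normalize_line(src[i]))
    }
  }
})

test_that("corpus splitting matches the floor rule and is deterministic", {
  ids <- sprintf("r%04d", seq_len(4188L))
  sp <- split_corpus(ids, 0.8, seed = 3L)
  expect_length(sp$train, 3350L)
  expect_length(sp$test, 838L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)

  expect_identical(sp, split_corpus(ids, 0.8, seed = 3L))
  expect_false(identical(sp, split_corpus(ids, 0.8, seed = 4L)))

  sp10 <- split_corpus(sprintf("x%d", 1:10), 0.8, seed = 1L)
  expect_equal(lengths(sp10), c(train = 8L, test = 2L))
  expect_equal(lengths(split_corpus(character(), 0.8, 1L)),
               c(train = 0L, test = 0L))
  # sizes always sum to N for odd fractions
  for (n in c(1L, 7L, 33L)) {
    spn <- split_corpus(as.character(seq_len(n)), 0.37, seed = 2L)
    expect_equal(sum(lengths(spn)), n)
    expect_length(spn$train, floor(n * 0.37))
  }
  expect_error(split_corpus(ids, 1.2), "train_fraction")
})
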