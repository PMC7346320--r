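test_that("longest dictionary hit wins: the compound phrase beats its parts", {
  lex <- annotation_lexicon()
  sp <- fmm_annotate("主动脉瓣,二尖瓣钙化", lex, report_id = "d1")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$etype, "aortic_mitral_calcification")
  expect_equal(c(sp$pos_b, sp$pos_e), c(0L, 10L))

  # without the compound entry the two component phrases do not both match
  sp2 <- fmm_annotate("患者二尖瓣钙化，主动脉瓣钙化",
                      lex, report_id = "d2")
  expect_equal(sp2$etype, c("mitral_calcification", "aortic_calcification"))

  # zero lexicon surfaces -> empty span list
  expect_equal(nrow(fmm_annotate("窦性心律不齐", lex)), 0L)
})

test_that("FMM matches the brute-force window-enumeration oracle", {
  set.seed(101)
  for (trial in seq_len(220L)) {
    case <- random_toy_case()
    lex <- lexicon(case$entries, registry = data.frame(code = case$entries$etype))
    got <- fmm_annotate(case$text, lex, report_id = "t")
    want <- fmm_oracle(case$text, case$entries)
    expect_equal(got[, c("pos_b", "pos_e", "etype")], want,
                 ignore_attr = TRUE)
    # spans disjoint and increasing
    if (nrow(got) > 1L) {
      expect_true(all(diff(got$pos_b) > 0))
      expect_true(all(got$pos_b[-1L] >= got$pos_e[-nrow(got)]))
    }
  }
})

test_that("adding a longer superstring phrase never shortens a match", {
  base <- lexicon(data.frame(surface = "二尖瓣狭窄", etype = "mitral_stenosis",
                             provenance = "seed"))
  longer <- merge_lexicon(base, data.frame(surface = "二尖瓣狭窄可能",
                                           etype = "mitral_stenosis",
                                           provenance = "manual"))
  text <- "提示二尖瓣狭窄可能。"
  s1 <- fmm_annotate(text, base)
  s2 <- fmm_annotate(text, longer)
  expect_equal(s1$pos_e - s1$pos_b, 5L)
  expect_equal(s2$pos_e - s2$pos_b, 7L)
  expect_true(all(s2$pos_e - s2$pos_b >= s1$pos_e - s1$pos_b))
})

test_that("spans_to_bio produces well-formed tags and round-trips", {
  sp <- data.frame(report_id = "r", pos_b = 0L, pos_e = 5L,
                   etype = "mitral_stenosis", stringsAsFactors = FALSE)
  ts <- spans_to_bio("二尖瓣狭窄。", sp, report_id = "r")
  expect_equal(ts$tags, c("B-mitral_stenosis", rep("I-mitral_stenosis", 4L), "O"))
  expect_equal(bio_to_spans(ts)[, c("pos_b", "pos_e", "etype")],
               sp[, c("pos_b", "pos_e", "etype")], ignore_attr = TRUE)

  # empty span list -> all O
  no_spans <- data.frame(report_id = character(), pos_b = integer(),
                         pos_e = integer(), etype = character())
  expect_true(all(spans_to_bio("窦性心律", no_spans)$tags == "O"))

  # adjacent same-type spans: the second must open with B
  adj <- data.frame(report_id = "r", pos_b = c(0L, 2L), pos_e = c(2L, 4L),
                    etype = "cardiac_enlargement", stringsAsFactors = FALSE)
  ts2 <- spans_to_bio("心脏增大", adj, report_id = "r")
  expect_equal(ts2$tags, c("B-cardiac_enlargement", "I-cardiac_enlargement",
                           "B-cardiac_enlargement", "I-cardiac_enlargement"))
  expect_equal(nrow(bio_to_spans(ts2)), 2L)
})

test_that("bio/span conversion is a bijection on random well-formed inputs", {
  set.seed(77)
  lex <- annotation_lexicon()
  cp <- generate_corpus(generator_config(n_reports = 15L, seed = 8L))
  pg <- normalize_corpus(cp$reports)
  for (id in names(pg)) {
    sp <- fmm_annotate(pg[[id]], lex)
    ts <- spans_to_bio(pg[[id]], sp)
    # well-formed BIO: every I is preceded by B/I of the same type
    bad <- vapply(seq_along(ts$tags), function(i) {
      t <- ts$tags[i]
      if (!startsWith(t, "I-")) return(FALSE)
      prev <- if (i > 1L) ts$tags[i - 1L] else "O"
      !(prev %in% paste0(c("B-", "I-"), substr(t, 3L, nchar(t))))
    }, TRUE)
    expect_false(any(bad))
    back <- bio_to_spans(ts)
    expect_equal(back, sp, ignore_attr = TRUE)
  }
})

test_that("ill-formed model output is repaired by I-to-B promotion", {
  ts <- structure(list(report_id = "r", chars = c("a", "b", "c"),
                       tags = c("O", "I-mitral_stenosis", "I-mitral_stenosis")),
                  class = "tag_sequence")
  sp <- bio_to_spans(ts)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$pos_b, sp$pos_e), c(1L, 3L))
  expect_equal(sp$etype, "mitral_stenosis")

  # type switch inside an I-run opens a new span
  ts2 <- structure(list(report_id = "r", chars = c("a", "b"),
                        tags = c("I-mitral_stenosis", "I-cardiac_enlargement")),
                   class = "tag_sequence")
  expect_equal(nrow(bio_to_spans(ts2)), 2L)

  # all-O decodes to nothing; unknown labels are an error
  ts3 <- structure(list(report_id = "r", chars = "a", tags = "O"),
                   class = "tag_sequence")
  expect_equal(nrow(bio_to_spans(ts3)), 0L)
  ts4 <- structure(list(report_id = "r", chars = "a", tags = "B-unknown"),
                   class = "tag_sequence")
  expect_error(bio_to_spans(ts4), "unknown tag")
})

test_that("CoNLL files round-trip and ragged lines are reported", {
  lex <- annotation_lexicon()
  texts <- c(r1 = "二尖瓣狭窄。", r2 = "心脏增大，室壁运动减弱",
             r3 = "窦性心律")
  seqs <- lapply(names(texts), function(id) {
    spans_to_bio(texts[[id]], fmm_annotate(texts[[id]], lex, id),
                 report_id = id)
  })
  tmp <- withr::local_tempfile(fileext = ".conll")
  write_conll(seqs, tmp)
  back <- read_conll(tmp)
  expect_equal(back, seqs, ignore_attr = TRUE)

  bad <- withr::local_tempfile()
  writeLines(c("# id = x", "a\tO\textra"), bad, useBytes = TRUE)
  expect_error(read_conll(bad), "line 2")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_length(read_conll(empty), 0L)
})

test_that("span TSV files round-trip including the family column", {
  sp <- data.frame(report_id = c("a", "b"), pos_b = c(0L, 3L),
                   pos_e = c(4L, 9L),
                   etype = c("mitral_stenosis", "cardiac_enlargement"),
                   stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_spans(sp, tmp)
  expect_equal(read_spans(tmp), sp, ignore_attr = TRUE)

  sp$family <- c(NA, "trailing_qualifier")
  write_spans(sp, tmp)
  expect_equal(names(read_spans(tmp)),
               c("report_id", "pos_b", "pos_e", "etype", "family"))
})
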