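test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_reports = 25L, seed = 13L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  c3 <- generate_corpus(generator_config(n_reports = 25L, seed = 14L))
  expect_false(identical(c1$reports, c3$reports))
})

test_that("all six report fields are populated and ids unique", {
  cp <- generate_corpus(generator_config(n_reports = 30L, seed = 2L))
  ids <- vapply(cp$reports, `[[`, "", "report_id")
  expect_false(anyDuplicated(ids) > 0)
  for (r in cp$reports[1:5]) {
    expect_true(all(nzchar(c(r$report_id, r$patient_id, r$exam_time,
                             r$exam_item, r$exam_category))))
    expect_gte(length(r$description), 1L)
    expect_gte(length(r$conclusion), 1L)
  }
})

test_that("gold spans sit inside their paragraphs and never cross the section boundary", {
  cp <- generate_corpus(generator_config(n_reports = 40L, seed = 3L,
                                         injection_rate = 0.2))
  pg <- normalize_corpus(cp$reports)
  for (r in seq_len(nrow(cp$gold))) {
    g <- cp$gold[r, ]
    p <- pg[[g$report_id]]
    expect_true(g$pos_b >= 0L && g$pos_b < g$pos_e && g$pos_e <= p$n)
    off <- p$offsets
    inside <- off$start <= g$pos_b & g$pos_e <= off$end
    expect_true(any(inside))  # each span lies within a single source line
  }
})

test_that("at injection rate 0 the gold standard equals FMM annotation exactly", {
  lex <- annotation_lexicon()
  cp <- generate_corpus(generator_config(n_reports = 150L, seed = 17L,
                                         injection_rate = 0), lex = lex)
  pg <- normalize_corpus(cp$reports)
  dict <- fmm_annotate_corpus(pg, lex)
  m <- strict_metrics(dict, cp$gold)
  expect_equal(m$overall$f1, 1)
  expect_equal(m$overall$n_pred, nrow(cp$gold))
  # and every gold surface is a lexicon entry of the right type
  surf <- span_surfaces(cp$gold, pg)
  hit <- match(surf, lex$entries$surface)
  expect_false(anyNA(hit))
  expect_equal(lex$entries$etype[hit], cp$gold$etype)
})

test_that("injected novel spans use surfaces the lexicon cannot produce", {
  lex <- annotation_lexicon()
  cp <- generate_corpus(generator_config(n_reports = 200L, seed = 23L,
                                         injection_rate = 0.3), lex = lex)
  expect_gt(sum(cp$gold$novel), 0L)
  pg <- normalize_corpus(cp$reports)
  novel_surf <- span_surfaces(cp$gold[cp$gold$novel, ], pg)
  expect_false(any(novel_surf %in% lex$entries$surface))
  expect_true(all(novel_surf %in% unlist(novel_variants())))
  # dictionary recall on novel spans is structurally zero
  dict <- fmm_annotate_corpus(pg, lex)
  expect_equal(strict_metrics(dict, cp$gold[cp$gold$novel, ])$overall$recall, 0)
})

test_that("paragraph lengths emulate the documented corpus scale", {
  cp <- generate_corpus(generator_config(n_reports = 1000L, seed = 29L))
  lens <- vapply(normalize_corpus(cp$reports), `[[`, 0L, "n")
  expect_gt(mean(lens), 177 * 0.85)
  expect_lt(mean(lens), 177 * 1.15)
  # line-count means track the documented 4 description / 3 conclusion lines
  nd <- vapply(cp$reports, function(r) length(r$description), 0L)
  nc <- vapply(cp$reports, function(r) length(r$conclusion), 0L)
  expect_equal(mean(nd), 4, tolerance = 0.15)
  expect_equal(mean(nc), 3, tolerance = 0.15)
})

test_that("no filler template contains an annotation-lexicon surface", {
  lex <- annotation_lexicon()
  fillers <- c(echoNER:::normal_findings(),
               vapply(echoNER:::description_clauses(),
                      function(cl) sprintf(cl$tpl, cl$lo), ""),
               echoNER:::evidence_prefixes(), echoNER:::evidence_suffixes())
  fillers <- vapply(fillers, echoNER:::normalize_line, "", USE.NAMES = FALSE)
  for (surface in lex$entries$surface) {
    expect_false(any(grepl(surface, fillers, fixed = TRUE)),
                 label = paste("lexicon surface leaked into filler:", surface))
  }
})

test_that("challenge injection instantiates every error family with tagged gold", {
  cp <- generate_corpus(generator_config(n_reports = 10L, seed = 31L))
  expect_identical(inject_error_cases(cp, 0L), cp)
  aug <- inject_error_cases(cp, 8L, seed = 7L)
  expect_length(aug$reports, 18L)
  fams <- c("long_dependency", "confusable_grammar", "out_of_distribution",
            "trailing_qualifier")
  expect_setequal(unique(aug$challenges$family), fams)
  # per 100 challenge reports each family appears at least once
  expect_true(all(table(aug$challenges$family) >= 2L))
  tagged <- aug$gold[!is.na(aug$gold$family), ]
  expect_setequal(unique(tagged$family),
                  setdiff(fams, "confusable_grammar"))
  # challenge gold spans decode to the documented hard surfaces
  pg <- normalize_corpus(aug$reports)
  surf <- span_surfaces(tagged, pg)
  expect_true("二尖瓣狭窄（轻度）" %in% surf)
  expect_true("二尖瓣前叶赘生物伴腱索断裂、瓣膜脱垂" %in% surf)
  # the trailing-qualifier form defeats strict dictionary matching
  dict <- fmm_annotate_corpus(pg, annotation_lexicon())
  tq <- tagged[tagged$family == "trailing_qualifier", ]
  expect_equal(strict_metrics(dict, tq)$overall$recall, 0)
})
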