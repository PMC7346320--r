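mk_spans <- function(n, ids = "d", type = "mitral_stenosis") {
  data.frame(report_id = rep_len(ids, n), pos_b = seq_len(n) * 10L,
             pos_e = seq_len(n) * 10L + 5L, etype = rep_len(type, n),
             stringsAsFactors = FALSE)
}

test_that("identical prediction and gold sets score perfect metrics", {
  s <- mk_spans(5L)
  m <- strict_metrics(s, s)
  expect_equal(m$overall$precision, 1)
  expect_equal(m$overall$recall, 1)
  expect_equal(m$overall$f1, 1)
  expect_equal(m$overall$n_correct, 5L)
})

test_that("metrics follow the worked arithmetic and the headline F1 identity", {
  # |S| = 4, |G| = 5, |S ∩ G| = 3
  gold <- mk_spans(5L)
  pred <- rbind(mk_spans(3L),
                data.frame(report_id = "d", pos_b = 99L, pos_e = 104L,
                           etype = "mitral_stenosis"))
  m <- strict_metrics(pred, gold)
  expect_equal(m$overall$precision, 0.75)
  expect_equal(m$overall$recall, 0.6)
  expect_equal(m$overall$f1, 2 * 0.75 * 0.6 / 1.35)

  # the reported precision/recall pair combines to the reported F1
  expect_equal(round(f1_score(98.03, 90.17), 2), 93.94)
})

test_that("strict matching requires all four quadruple fields", {
  gold <- mk_spans(1L)
  for (delta in list(c("report_id", "other"), c("pos_b", 11L),
                     c("pos_e", 16L), c("etype", "cardiac_enlargement"))) {
    pred <- gold
    pred[[delta[[1L]]]] <- delta[[2L]]
    expect_equal(strict_metrics(pred, gold)$overall$n_correct, 0L)
  }
})

test_that("empty sets follow the zero conventions", {
  none <- mk_spans(0L)
  some <- mk_spans(2L)
  expect_equal(strict_metrics(none, some)$overall$precision, 0)
  expect_equal(strict_metrics(some, none)$overall$recall, 0)
  expect_equal(strict_metrics(none, none)$overall$f1, 0)
})

test_that("precision/recall symmetry and monotonicity properties hold", {
  set.seed(31)
  for (trial in seq_len(25L)) {
    g <- mk_spans(sample.int(8L, 1L))
    s <- g[sample(nrow(g), sample.int(nrow(g), 1L)), , drop = FALSE]
    extra <- data.frame(report_id = "d", pos_b = 500L + trial,
                        pos_e = 505L + trial, etype = "mitral_stenosis")
    m <- strict_metrics(s, g)
    # swapping roles swaps precision and recall
    m_swap <- strict_metrics(g, s)
    expect_equal(m$overall$precision, m_swap$overall$recall)
    # adding a correct span never hurts
    missing_rows <- g[!(paste(g$pos_b) %in% paste(s$pos_b)), , drop = FALSE]
    if (nrow(missing_rows)) {
      m_plus <- strict_metrics(rbind(s, missing_rows[1L, ]), g)
      expect_gte(m_plus$overall$precision, m$overall$precision - 1e-12)
      expect_gte(m_plus$overall$recall, m$overall$recall)
      expect_gte(m_plus$overall$f1, m$overall$f1)
    }
    # adding an incorrect span never raises precision
    m_fp <- strict_metrics(rbind(s, extra), g)
    expect_lte(m_fp$overall$precision, m$overall$precision + 1e-12)
    # F1 is bounded by the arithmetic mean and collapses when P = R
    o <- m$overall
    expect_lte(o$f1, (o$precision + o$recall) / 2 + 1e-12)
  }
  mm <- strict_metrics(mk_spans(3L), mk_spans(3L))
  expect_equal(mm$overall$f1, mm$overall$precision)
})

test_that("per-type counts pool to the overall micro counts", {
  pred <- rbind(mk_spans(3L, type = "mitral_stenosis"),
                mk_spans(2L, ids = "e", type = "cardiac_enlargement"))
  gold <- rbind(mk_spans(4L, type = "mitral_stenosis"),
                mk_spans(1L, ids = "e", type = "cardiac_enlargement"))
  m <- strict_metrics(pred, gold)
  expect_equal(sum(m$per_type$n_pred), m$overall$n_pred)
  expect_equal(sum(m$per_type$n_gold), m$overall$n_gold)
  expect_equal(sum(m$per_type$n_correct), m$overall$n_correct)
  expect_true(all(m$per_type$precision >= 0 & m$per_type$precision <= 1))
})

test_that("novel phrase reporting filters lexicon-covered surfaces and conserves counts", {
  lex <- annotation_lexicon()
  texts <- list(
    r1 = structure(list(report_id = "r1", text = "二尖瓣中-重度狭窄，二尖瓣狭窄",
                        n = 15L), class = "echo_paragraph"),
    r2 = structure(list(report_id = "r2", text = "二尖瓣中-重度狭窄",
                        n = 9L), class = "echo_paragraph"))
  pred <- data.frame(
    report_id = c("r1", "r1", "r2"),
    pos_b = c(0L, 10L, 0L), pos_e = c(9L, 15L, 9L),
    etype = "mitral_stenosis", stringsAsFactors = FALSE)
  nov <- novel_phrases(pred, texts, lex)
  expect_equal(nrow(nov), 1L)
  expect_equal(nov$surface, "二尖瓣中-重度狭窄")
  expect_equal(nov$count, 2L)
  n_unknown <- sum(!(span_surfaces(pred, texts) %in% lex$entries$surface))
  expect_equal(sum(nov$count), n_unknown)

  # all predictions lexicon-covered -> empty report
  pred_known <- pred[2L, , drop = FALSE]
  expect_equal(nrow(novel_phrases(pred_known, texts, lex)), 0L)
  # spans outside the paragraph are an error
  bad <- pred; bad$pos_e[1L] <- 99L
  expect_error(novel_phrases(bad, texts, lex), "outside")
})

test_that("method comparison tables line up per-type recalls", {
  pred <- mk_spans(3L)
  gold <- mk_spans(4L)
  m1 <- strict_metrics(pred, gold)
  m2 <- strict_metrics(gold, gold)
  comp <- compare_methods(list(dict = m1, model = m2))
  expect_equal(nrow(comp), nrow(m1$per_type) + 1L)
  expect_equal(comp$model[comp$etype == "overall"], 1)
  expect_equal(comp$dict[comp$etype == "mitral_stenosis"], 0.75)
  # identical inputs give identical columns
  comp2 <- compare_methods(list(a = m1, b = m1))
  expect_equal(comp2$a, comp2$b)
  # dictionary on novel-only gold has zero recall everywhere
  novel_gold <- data.frame(report_id = "z", pos_b = 0L, pos_e = 8L,
                           etype = "mitral_stenosis")
  m0 <- strict_metrics(mk_spans(0L), novel_gold)
  expect_true(all(compare_methods(list(dict = m0))$dict == 0))
})
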