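test_that("packaged lexicon has the documented seed composition", {
  lex <- default_lexicon()
  prov <- count_lexicon(lex, "provenance")
  expect_equal(prov$n[prov$key == "seed"], 27L)
  seed <- lex$entries[lex$entries$provenance == "seed", ]
  expect_equal(length(unique(seed$etype)), 20L)
  expect_equal(sum(count_lexicon(lex, "etype")$n), nrow(lex$entries))
  expect_equal(lex$max_len, max(nchar(lex$entries$surface)))
  # counts conservation over every key
  for (key in c("etype", "provenance", "category")) {
    expect_equal(sum(count_lexicon(lex, key)$n), nrow(lex$entries))
  }
})

test_that("annotation lexicon covers exactly the modeled types", {
  alex <- annotation_lexicon()
  expect_setequal(unique(alex$entries$etype), entity_types()$code)
  expect_true(all(c("主动脉瓣、二尖瓣钙化",
                    "主动脉瓣,二尖瓣钙化") %in% alex$entries$surface))
})

test_that("lexicon TSV round-trips and rejects conflicting surfaces", {
  lex <- default_lexicon()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, tmp)
  back <- read_lexicon(tmp)
  expect_equal(back$entries[order(back$entries$surface), ],
               lex$entries[order(lex$entries$surface), ],
               ignore_attr = TRUE)
  expect_equal(back$max_len, lex$max_len)

  # a surface mapped to two types is a validation error with line numbers
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("二尖瓣狭窄\tmitral_stenosis\tseed",
               "二尖瓣狭窄\tmitral_prolapse\tseed"),
             dup, useBytes = TRUE)
  expect_error(read_lexicon(dup), "line 2")

  # unknown entity code is named with its line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("二尖瓣狭窄\tnot_a_type\tseed", bad,
             useBytes = TRUE)
  expect_error(read_lexicon(bad), "not_a_type")

  # empty file -> empty lexicon with max_len 0
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  elex <- read_lexicon(empty)
  expect_equal(nrow(elex$entries), 0L)
  expect_equal(elex$max_len, 0L)
})

test_that("regex harvesting matches graded phrases but not hyphenated ones", {
  pats <- data.frame(pattern = "二尖瓣[\\u4e00-\\u9fa5]*狭窄",
                     etype = "mitral_stenosis", stringsAsFactors = FALSE)
  lines <- c("超声提示二尖瓣轻度狭窄。", "二尖瓣中度狭窄",
             "可见二尖瓣重度狭窄改变")
  hv <- harvest(pats, lines)
  expect_setequal(hv$surface, c("二尖瓣轻度狭窄", "二尖瓣中度狭窄",
                                "二尖瓣重度狭窄"))
  expect_true(all(hv$provenance == "harvested"))

  # the CJK wildcard class excludes the hyphen
  expect_equal(nrow(harvest(pats, "二尖瓣中-重度狭窄")), 0L)
  # and the empty corpus harvests nothing
  expect_equal(nrow(harvest(pats, character())), 0L)
})

test_that("harvest is deterministic, idempotent and self-consistent", {
  pats <- default_patterns()
  lines <- c("二尖瓣轻度狭窄，主动脉瓣钙化", "二尖瓣前叶脱垂可能",
             "节段性室壁运动异常", "扩张性心肌病")
  h1 <- harvest(pats, lines)
  h2 <- harvest(pats, lines)
  expect_identical(h1, h2)
  # harvesting from the harvested surfaces alone adds nothing new
  h3 <- harvest(pats, h1$surface)
  expect_setequal(h3$surface, h1$surface)
  # every harvested surface re-matches its originating pattern exactly
  for (r in seq_len(nrow(h1))) {
    pat <- pats$pattern[pats$etype == h1$etype[r]][1L]
    rx <- echoNER:::compile_harvest_pattern(pat)
    m <- regmatches(h1$surface[r], regexpr(rx, h1$surface[r], perl = TRUE))
    expect_equal(m, h1$surface[r])
  }
})

test_that("non-compiling patterns are configuration errors naming the pattern", {
  bad <- data.frame(pattern = "二尖瓣[", etype = "mitral_stenosis")
  expect_error(harvest(bad, "x"), "does not compile")
  expect_error(harvest(bad, "x"), "二尖瓣")
})

test_that("merging harvested entries keeps existing surfaces (idempotent)", {
  lex <- annotation_lexicon()
  hv <- harvest(default_patterns(),
                c("二尖瓣轻度狭窄", "二尖瓣中度脱垂"))
  merged <- merge_lexicon(lex, hv)
  expect_true("二尖瓣中度脱垂" %in% merged$entries$surface)
  again <- merge_lexicon(merged, hv)
  expect_equal(nrow(again$entries), nrow(merged$entries))
  # existing entry's provenance wins
  e <- merged$entries[merged$entries$surface == "二尖瓣轻度狭窄", ]
  expect_equal(e$provenance, "harvested")
  expect_equal(e$etype, "mitral_stenosis")
})
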