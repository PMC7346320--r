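#' Configuration for the synthetic echocardiograph-report generator
#'
#' The generator emulates the documented structure of the hospital corpus the
#' pipeline was designed for (which cannot be redistributed): per report, an
#' average of 4 ultrasound-description lines of about 34 characters built
#' from numeric measurement clauses (so digits, ASCII letters and spaces
#' exercise the normalization rules), and an average of 3 short
#' ultrasound-conclusion lines of about 8 characters, most carrying an
#' evidence phrase, merging to a paragraph of roughly 177 characters.
#' Evidence phrases are drawn from the annotation lexicon with
#' frequency-ranked weights (a geometric profile over the modeled types in
#' their corpus-frequency order); with probability `injection_rate` a
#' mention instead uses a novel surface variant absent from the lexicon
#' (hyphenated grades, synonym suffixes, reordered qualifiers), flagged as
#' novel in the gold standard.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param injection_rate Probability that an evidence mention uses a novel
#'   variant (0 disables injection, making gold identical to forward-maximum
#'   matching output).
#' @param desc_lines_mean,concl_lines_mean Mean line counts (shifted-Poisson
#'   distributed: `1 + rpois(mean - 1)`).
#' @param p_conclusion_evidence Probability a conclusion line carries an
#'   evidence phrase rather than a normal finding.
#' @param p_description_evidence Probability a description line carries an
#'   appended evidence clause.
#' @param evidence_decay Geometric decay of the per-type frequency weights.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 1000L, seed = 1L,
                             injection_rate = 0.05,
                             desc_lines_mean = 4, concl_lines_mean = 3,
                             p_conclusion_evidence = 0.65,
                             p_description_evidence = 0.2,
                             evidence_decay = 0.78) {
  stopifnot(n_reports >= 0, injection_rate >= 0, injection_rate <= 1,
            desc_lines_mean >= 1, concl_lines_mean >= 1,
            p_conclusion_evidence >= 0, p_conclusion_evidence <= 1,
            p_description_evidence >= 0, p_description_evidence <= 1,
            evidence_decay > 0, evidence_decay <= 1)
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 injection_rate = injection_rate,
                 desc_lines_mean = desc_lines_mean,
                 concl_lines_mean = concl_lines_mean,
                 p_conclusion_evidence = p_conclusion_evidence,
                 p_description_evidence = p_description_evidence,
                 evidence_decay = evidence_decay),
            class = "generator_config")
}

# Numeric-measurement description clauses; {d} is an integer placeholder.
description_clauses <- function() {
  list(
    list(tpl = "左房前后径 %dmm", lo = 25, hi = 45),
    list(tpl = "左室舒张末内径 %dmm", lo = 40, hi = 60),
    list(tpl = "室间隔厚度 %dmm", lo = 8, hi = 13),
    list(tpl = "左室后壁厚度 %dmm", lo = 8, hi = 12),
    list(tpl = "主动脉根部内径 %dmm", lo = 25, hi = 38),
    list(tpl = "升主动脉内径 %dmm", lo = 28, hi = 40),
    list(tpl = "肺动脉主干内径 %dmm", lo = 18, hi = 28),
    list(tpl = "EF 值 %d%%", lo = 50, hi = 70),
    list(tpl = "心率 %d次/分", lo = 55, hi = 95)
  )
}

normal_findings <- function() {
  c("心内结构未见明显异常",
    "左室收缩功能正常",
    "静息状态下心功能正常",
    "各瓣膜启闭运动正常",
    "升主动脉增宽",
    "左室舒张功能减低",
    "心包腔未见明显积液")
}

evidence_prefixes <- function() c("考虑", "提示")
evidence_suffixes <- function() c("可能")

#' Novel surface variants per entity type
#'
#' Surface forms that sonographers produce but the lexicon does not cover:
#' hyphenated grade ranges, synonym suffixes, reordered qualifiers and
#' trailing qualifiers.  None of them is a lexicon entry, so dictionary
#' recall on spans using them is structurally zero.
#' @return Named list: type code -> character vector of variant surfaces.
#' @export
novel_variants <- function() {
  list(
    mitral_stenosis = c("二尖瓣中-重度狭窄", "二尖瓣轻-中度狭窄",
                        "二尖瓣狭窄（轻度）"),
    mitral_prolapse = c("二尖瓣中度脱垂", "二尖瓣重度脱垂"),
    aortic_calcification = c("主动脉瓣退行性病变", "主动脉瓣增厚、钙化"),
    mitral_calcification = c("二尖瓣退行性病变"),
    myocardial_infarction = c("节段性运动异常"),
    aortic_mitral_calcification = c("二尖瓣、主动脉瓣增厚,退行性变"),
    wall_hypokinesis = c("室壁运动稍减弱"),
    cardiac_enlargement = c("心脏轻度增大")
  )
}

# Draw an evidence mention: list(surface, etype, novel).
draw_evidence <- function(lex_by_type, weights, injection_rate, novels) {
  ty <- sample(names(weights), 1L, prob = weights)
  pool <- novels[[ty]]
  if (!is.null(pool) && stats::runif(1) < injection_rate) {
    list(surface = sample(pool, 1L), etype = ty, novel = TRUE)
  } else {
    list(surface = sample(lex_by_type[[ty]], 1L), etype = ty, novel = FALSE)
  }
}

#' Generate a synthetic corpus with gold spans
#'
#' Assembles reports from templated measurement sentences (description) and
#' evidence / normal-finding phrases (conclusion); computes the gold span
#' coordinates of every evidence mention directly against the normalized
#' paragraph layout produced by [normalize_report()] (description lines
#' concatenated, conclusion lines joined with the full-width comma).  At
#' `injection_rate = 0` the gold standard coincides exactly with
#' forward-maximum-matching annotation, which makes end-to-end recovery
#' experiments well-posed; at positive rates the flagged novel spans are
#' invisible to the dictionary by construction.
#'
#' @param config A [generator_config()].
#' @param lex The annotation lexicon supplying evidence surfaces (default
#'   [annotation_lexicon()]).
#' @return A list of class `synthetic_corpus`: `reports` (list of
#'   `echo_report`), `gold` (span data frame with extra logical column
#'   `novel`), and `challenges` (empty data frame; see
#'   [inject_error_cases()]).
#' @export
generate_corpus <- function(config = generator_config(),
                            lex = annotation_lexicon()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lex, "echo_lexicon"))
  types <- entity_types()$code
  lex_by_type <- split(lex$entries$surface, lex$entries$etype)[types]
  missing_t <- types[vapply(lex_by_type, is.null, TRUE)]
  if (length(missing_t)) {
    stop("no lexicon surfaces for type(s): ", paste(missing_t, collapse = ", "))
  }
  weights <- config$evidence_decay^(seq_along(types) - 1L)
  names(weights) <- types
  novels <- novel_variants()
  clauses <- description_clauses()
  findings <- normal_findings()

  with_seed(config$seed, {
    reports <- vector("list", config$n_reports)
    gold_rows <- list()
    for (r in seq_len(config$n_reports)) {
      rid <- sprintf("R%05d", r)
      # --- description lines: measurement clauses + occasional evidence
      n_desc <- 1L + stats::rpois(1L, config$desc_lines_mean - 1)
      desc <- character(n_desc)
      desc_marks <- vector("list", n_desc)   # evidence offsets within line
      for (j in seq_len(n_desc)) {
        n_cl <- sample(2:4, 1L, prob = c(0.1, 0.45, 0.45))
        picks <- sample(seq_along(clauses), n_cl)
        parts <- vapply(picks, function(p) {
          cl <- clauses[[p]]
          sprintf(cl$tpl, sample(cl$lo:cl$hi, 1L))
        }, "")
        raw <- paste(parts, collapse = "，")
        mark <- NULL
        if (stats::runif(1) < config$p_description_evidence) {
          ev <- draw_evidence(lex_by_type, weights, config$injection_rate,
                              novels)
          pre <- paste0(raw, "，提示")
          mark <- list(ev = ev, off = nchar(normalize_line(pre)))
          raw <- paste0(pre, ev$surface)
        }
        desc[j] <- paste0(raw, "。")
        desc_marks[j] <- list(mark)
      }
      # --- conclusion lines: evidence phrase or normal finding
      n_concl <- 1L + stats::rpois(1L, config$concl_lines_mean - 1)
      concl <- character(n_concl)
      concl_marks <- vector("list", n_concl)
      for (j in seq_len(n_concl)) {
        if (stats::runif(1) < config$p_conclusion_evidence) {
          ev <- draw_evidence(lex_by_type, weights, config$injection_rate,
                              novels)
          pre <- if (stats::runif(1) < 0.3)
            sample(evidence_prefixes(), 1L) else ""
          suf <- if (stats::runif(1) < 0.15)
            sample(evidence_suffixes(), 1L) else ""
          concl[j] <- paste0(pre, ev$surface, suf)
          concl_marks[j] <- list(list(ev = ev, off = nchar(pre)))
        } else {
          concl[j] <- sample(findings, 1L)
        }
      }
      reports[[r]] <- echo_report(
        report_id = rid, patient_id = sprintf("P%05d", sample.int(9000L, 1L)),
        exam_time = sprintf("20%02d-%02d-%02d", sample(9:18, 1L),
                            sample.int(12L, 1L), sample.int(28L, 1L)),
        exam_item = "经胸超声心动图", exam_category = "超声",
        description = desc, conclusion = concl
      )
      # --- gold offsets on the normalized paragraph layout
      desc_norm_len <- vapply(desc, function(l) nchar(normalize_line(l)), 0L,
                              USE.NAMES = FALSE)
      concl_norm_len <- vapply(concl, function(l) nchar(normalize_line(l)),
                               0L, USE.NAMES = FALSE)
      desc_start <- cumsum(c(0L, desc_norm_len))[seq_len(n_desc)]
      concl_block <- sum(desc_norm_len)
      concl_start <- concl_block +
        cumsum(c(0L, concl_norm_len + 1L))[seq_len(n_concl)]  # +1 per "，"
      for (j in seq_len(n_desc)) {
        mk <- desc_marks[[j]]
        if (!is.null(mk)) {
          b <- desc_start[j] + mk$off
          gold_rows[[length(gold_rows) + 1L]] <- data.frame(
            report_id = rid, pos_b = b, pos_e = b + nchar(mk$ev$surface),
            etype = mk$ev$etype, novel = mk$ev$novel,
            stringsAsFactors = FALSE)
        }
      }
      for (j in seq_len(n_concl)) {
        mk <- concl_marks[[j]]
        if (!is.null(mk)) {
          b <- concl_start[j] + mk$off
          gold_rows[[length(gold_rows) + 1L]] <- data.frame(
            report_id = rid, pos_b = b, pos_e = b + nchar(mk$ev$surface),
            etype = mk$ev$etype, novel = mk$ev$novel,
            stringsAsFactors = FALSE)
        }
      }
    }
    gold <- if (length(gold_rows)) {
      do.call(rbind, c(gold_rows, list(make.row.names = FALSE)))
    } else {
      cbind(span_frame(character()), data.frame(novel = logical()))
    }
    structure(list(reports = reports, gold = gold,
                   challenges = data.frame(report_id = character(),
                                           family = character(),
                                           stringsAsFactors = FALSE)),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("synthetic_corpus: ", length(x$reports), " reports, ",
      nrow(x$gold), " gold spans (", sum(x$gold$novel), " novel), ",
      nrow(x$challenges), " challenge reports\n", sep = "")
  invisible(x)
}

# The four documented error families with their gold standard.
challenge_families <- function() {
  list(
    long_dependency = list(
      lines = "二尖瓣前叶赘生物伴腱索断裂、瓣膜脱垂",
      gold = list(list(line = 1L, off = 0L,
                       surface = "二尖瓣前叶赘生物伴腱索断裂、瓣膜脱垂",
                       etype = "mitral_prolapse"))),
    confusable_grammar = list(
      lines = c("阔瓣术后", "三尖瓣脱垂"),
      gold = list()),
    out_of_distribution = list(
      lines = c("左室肥厚", "室壁运动僵直"),
      gold = list(list(line = 1L, off = 0L, surface = "左室肥厚",
                       etype = "cardiac_enlargement"),
                  list(line = 2L, off = 0L, surface = "室壁运动僵直",
                       etype = "wall_hypokinesis"))),
    trailing_qualifier = list(
      lines = "二尖瓣狭窄（轻度）",
      gold = list(list(line = 1L, off = 0L, surface = "二尖瓣狭窄（轻度）",
                       etype = "mitral_stenosis")))
  )
}

#' Add challenge reports instantiating the documented error families
#'
#' Appends reports containing the four families of hard cases observed in
#' model error analysis: long-dependency sentences, confusable grammatical
#' structure, out-of-distribution phrases, and trailing-qualifier forms.
#' Challenge gold spans carry a `family` tag for per-family recall
#' reporting; the confusable-grammar family contributes distractor text with
#' no gold span (it probes false positives).  With `n_challenge = 0` the
#' corpus is returned unchanged.
#'
#' @param corpus A `synthetic_corpus`.
#' @param n_challenge Number of challenge reports to append; the four
#'   families are cycled deterministically so each is present at least once
#'   per four reports.
#' @param seed Seed for the filler content of challenge reports.
#' @return The augmented `synthetic_corpus` (gold gains a `family` column;
#'   `challenges` lists report id and family).
#' @export
inject_error_cases <- function(corpus, n_challenge = 0L, seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"), n_challenge >= 0)
  if (n_challenge == 0L) return(corpus)
  fams <- challenge_families()
  clauses <- description_clauses()
  gold <- corpus$gold
  if (!("family" %in% names(gold))) gold$family <- NA_character_
  new_reports <- list()
  chal_rows <- list()
  with_seed(seed, {
    for (i in seq_len(n_challenge)) {
      fam_name <- names(fams)[((i - 1L) %% length(fams)) + 1L]
      fam <- fams[[fam_name]]
      rid <- sprintf("C%05d", i)
      picks <- sample(seq_along(clauses), 3L)
      desc <- paste0(paste(vapply(picks, function(p) {
        cl <- clauses[[p]]
        sprintf(cl$tpl, sample(cl$lo:cl$hi, 1L))
      }, ""), collapse = "，"), "。")
      new_reports[[length(new_reports) + 1L]] <- echo_report(
        report_id = rid, patient_id = sprintf("P%05d", sample.int(9000L, 1L)),
        exam_time = "2018-01-01", exam_item = "经胸超声心动图",
        exam_category = "超声",
        description = desc, conclusion = fam$lines
      )
      desc_len <- nchar(normalize_line(desc))
      concl_len <- vapply(fam$lines, function(l) nchar(normalize_line(l)),
                          0L, USE.NAMES = FALSE)
      concl_start <- desc_len +
        cumsum(c(0L, concl_len + 1L))[seq_along(fam$lines)]
      for (g in fam$gold) {
        b <- concl_start[g$line] + g$off
        gold <- rbind(gold, data.frame(
          report_id = rid, pos_b = b, pos_e = b + nchar(g$surface),
          etype = g$etype, novel = TRUE, family = fam_name,
          stringsAsFactors = FALSE))
      }
      chal_rows[[length(chal_rows) + 1L]] <- data.frame(
        report_id = rid, family = fam_name, stringsAsFactors = FALSE)
    }
  })
  corpus$reports <- c(corpus$reports, new_reports)
  corpus$gold <- gold
  corpus$challenges <- rbind(corpus$challenges,
                             do.call(rbind, chal_rows))
  rownames(corpus$gold) <- NULL
  corpus
}
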