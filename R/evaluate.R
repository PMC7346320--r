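#' Strict span-quadruple evaluation
#'
#' A predicted span counts as correct only if it is strictly equivalent to a
#' gold span: the report id, the start position, the end position and the
#' entity type must all match.  With prediction set S and gold set G,
#' `P = |S∩G|/|S|`, `R = |S∩G|/|G|`, `F1 = 2PR/(P+R)`; an empty denominator
#' yields 0 by convention.  Overall metrics are micro-averaged (pooled
#' counts); macro averages over types are also reported, labeled as such.
#'
#' @param pred Span data frame (the prediction set S).
#' @param gold Span data frame (the gold set G).
#' @param types Character vector of entity-type codes for the per-type table
#'   (default: the modeling registry; types absent from both sets get
#'   all-zero rows).
#' @return A list of class `metrics_report`: `per_type` (data frame with
#'   columns `etype`, `n_pred`, `n_gold`, `n_correct`, `precision`,
#'   `recall`, `f1`), `overall` (micro-averaged row), `macro` (macro
#'   averages), and the pooled counts.
#' @examples
#' s <- data.frame(report_id = "r1", pos_b = 0L, pos_e = 5L,
#'                 etype = "mitral_stenosis")
#' strict_metrics(s, s)$overall$f1  # 1
#' @export
strict_metrics <- function(pred, gold, types = entity_types()$code) {
  pred <- unique_spans(pred)
  gold <- unique_spans(gold)
  types <- union(types, unique(c(pred$etype, gold$etype)))
  key <- function(d) paste(d$report_id, d$pos_b, d$pos_e, d$etype, sep = "\r")
  inter <- intersect(key(pred), key(gold))
  per <- lapply(types, function(ty) {
    sp <- pred[pred$etype == ty, , drop = FALSE]
    sg <- gold[gold$etype == ty, , drop = FALSE]
    tp <- length(intersect(key(sp), key(sg)))
    c(n_pred = nrow(sp), n_gold = nrow(sg), n_correct = tp)
  })
  per <- as.data.frame(do.call(rbind, per))
  per <- cbind(data.frame(etype = types, stringsAsFactors = FALSE), per)
  prf <- function(tp, np, ng) {
    p <- if (np > 0) tp / np else 0
    r <- if (ng > 0) tp / ng else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  m <- t(mapply(prf, per$n_correct, per$n_pred, per$n_gold))
  per$precision <- m[, "precision"]; per$recall <- m[, "recall"]
  per$f1 <- m[, "f1"]
  ov <- prf(length(inter), nrow(pred), nrow(gold))
  overall <- list(n_pred = nrow(pred), n_gold = nrow(gold),
                  n_correct = length(inter),
                  precision = ov[["precision"]], recall = ov[["recall"]],
                  f1 = ov[["f1"]])
  macro <- list(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1))
  structure(list(per_type = per, overall = overall, macro = macro),
            class = "metrics_report")
}

unique_spans <- function(spans) {
  if (is.null(spans) || !nrow(spans)) return(span_frame(character()))
  spans <- spans[, c("report_id", "pos_b", "pos_e", "etype")]
  unique(spans)
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  o <- x$overall
  cat(sprintf("strict span metrics (micro): P=%.*f R=%.*f F1=%.*f  (|S|=%d |G|=%d |S∩G|=%d)\n",
              digits, o$precision, digits, o$recall, digits, o$f1,
              o$n_pred, o$n_gold, o$n_correct))
  invisible(x)
}

#' F1 from precision and recall
#'
#' The harmonic mean `2PR/(P+R)` (0 when `P + R = 0`).  Accepts either
#' proportions or percentages; e.g. precision 98.03% and recall 90.17%
#' combine to an F1 of 93.94%.
#' @param precision,recall Numeric scalars (same scale).
#' @return Numeric scalar on the input scale.
#' @examples
#' round(f1_score(98.03, 90.17), 2)  # 93.94
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Write a metrics report as TSV
#'
#' Per-type rows followed by `overall_micro` and `overall_macro` rows.
#' @param metrics A `metrics_report`.
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  per <- metrics$per_type
  rows <- sprintf("%s\t%d\t%d\t%d\t%.6f\t%.6f\t%.6f", per$etype, per$n_pred,
                  per$n_gold, per$n_correct, per$precision, per$recall, per$f1)
  o <- metrics$overall; m <- metrics$macro
  rows <- c(rows,
            sprintf("overall_micro\t%d\t%d\t%d\t%.6f\t%.6f\t%.6f",
                    o$n_pred, o$n_gold, o$n_correct, o$precision, o$recall, o$f1),
            sprintf("overall_macro\tNA\tNA\tNA\t%.6f\t%.6f\t%.6f",
                    m$precision, m$recall, m$f1))
  write_utf8_lines(
    c("etype\tn_pred\tn_gold\tn_correct\tprecision\trecall\tf1", rows), path)
}

#' Report predicted surfaces absent from the lexicon
#'
#' The model's novel-phrase findings: surfaces of predicted spans whose text
#' is not an exact lexicon entry, deduplicated with frequencies, sorted by
#' count (decreasing) then surface.
#'
#' @param pred Span data frame of predictions.
#' @param paragraphs Named list of `echo_paragraph` objects.
#' @param lex The `echo_lexicon` the predictions are compared against.
#' @return Data frame with columns `surface`, `etype`, `count`.
#' @export
novel_phrases <- function(pred, paragraphs, lex) {
  if (!nrow(pred)) {
    return(data.frame(surface = character(), etype = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  surf <- span_surfaces(pred, paragraphs)
  known <- surf %in% lex$entries$surface
  d <- data.frame(surface = surf[!known], etype = pred$etype[!known],
                  stringsAsFactors = FALSE)
  if (!nrow(d)) {
    return(data.frame(surface = character(), etype = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(count = rep(1L, nrow(d))),
                   by = list(surface = d$surface, etype = d$etype), FUN = sum)
  agg$count <- as.integer(agg$count)
  agg[order(-agg$count, agg$surface), c("surface", "etype", "count")] |>
    `rownames<-`(NULL)
}

#' Per-type recall comparison across methods
#'
#' Side-by-side recall of several evaluation runs sharing a type registry —
#' e.g. the clinician-seed dictionary, the regex-extended dictionary and the
#' trained model — one row per type plus an overall (micro) row.
#'
#' @param metrics_list Named list of `metrics_report` objects.
#' @return Data frame: column `etype`, then one recall column per method.
#' @export
compare_methods <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L, !is.null(names(metrics_list)),
            all(nzchar(names(metrics_list))))
  base_types <- metrics_list[[1L]]$per_type$etype
  for (m in metrics_list) {
    if (!identical(sort(m$per_type$etype), sort(base_types))) {
      stop("metrics reports do not share the same type registry")
    }
  }
  out <- data.frame(etype = c(base_types, "overall"), stringsAsFactors = FALSE)
  for (nm in names(metrics_list)) {
    m <- metrics_list[[nm]]
    rec <- m$per_type$recall[match(base_types, m$per_type$etype)]
    out[[nm]] <- c(rec, m$overall$recall)
  }
  out
}

#' Write a method-comparison table as TSV
#' @param comparison Data frame from [compare_methods()].
#' @param path File path.
#' @export
write_comparison <- function(comparison, path) {
  header <- paste(names(comparison), collapse = "\t")
  fmt_cell <- function(x) if (is.numeric(x)) sprintf("%.6f", x) else as.character(x)
  body <- vapply(seq_len(nrow(comparison)), function(i) {
    paste(vapply(comparison[i, ], fmt_cell, ""), collapse = "\t")
  }, "")
  write_utf8_lines(c(header, body), path)
}
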