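#' Forward-maximum-matching annotation
#'
#' Greedy left-to-right dictionary matching: at each character position the
#' longest lexicon surface starting there is matched (window lengths are
#' tried from `min(max_len, n - i)` down to 1); on a hit a span is emitted
#' and the scan advances past it, otherwise it advances one character.  The
#' result is the weak supervision used to train the tagger: deterministic,
#' disjoint spans in increasing start order.  Matching is exact on the
#' normalized text; recovering variant surfaces the dictionary misses is the
#' sequence model's job.
#'
#' @param paragraph An `echo_paragraph` (or a plain string, in which case
#'   `report_id` is taken from the `report_id` argument).
#' @param lex An `echo_lexicon`.
#' @param report_id Report id used when `paragraph` is a plain string.
#' @return A span data frame with columns `report_id`, `pos_b`, `pos_e`
#'   (0-based half-open character interval), `etype` — the span quadruple
#'   ⟨d, pos_b, pos_e, c⟩.
#' @examples
#' lex <- annotation_lexicon()
#' fmm_annotate("主动脉瓣,二尖瓣钙化", lex, report_id = "r1")
#' @export
fmm_annotate <- function(paragraph, lex, report_id = "") {
  stopifnot(inherits(lex, "echo_lexicon"))
  if (inherits(paragraph, "echo_paragraph")) {
    text <- paragraph$text
    report_id <- paragraph$report_id
  } else {
    text <- nfc(as.character(paragraph))
  }
  idx <- lexicon_index(lex)
  chars <- chars_of(text)
  n <- length(chars)
  pos_b <- integer(); pos_e <- integer(); etype <- character()
  i <- 1L
  while (i <= n) {
    cands <- idx$by_first[[chars[i]]]
    hit_len <- 0L
    if (!is.null(cands)) {
      for (r in seq_len(nrow(cands))) {        # sorted by decreasing length
        len <- cands$len[r]
        if (len > n - i + 1L) next
        if (paste0(chars[i:(i + len - 1L)], collapse = "") == cands$surface[r]) {
          hit_len <- len
          pos_b <- c(pos_b, i - 1L)
          pos_e <- c(pos_e, i - 1L + len)
          etype <- c(etype, cands$etype[r])
          break
        }
      }
    }
    i <- i + if (hit_len > 0L) hit_len else 1L
  }
  span_frame(report_id, pos_b, pos_e, etype)
}

# First-character index over lexicon surfaces, surfaces sorted by
# decreasing length within each bucket (longest-first matching).
lexicon_index <- function(lex) {
  e <- lex$entries
  if (!nrow(e)) return(list(by_first = list()))
  first <- substr(e$surface, 1L, 1L)
  len <- nchar(e$surface)
  by_first <- split(data.frame(surface = e$surface, etype = e$etype,
                               len = len, stringsAsFactors = FALSE), first)
  by_first <- lapply(by_first, function(d) d[order(-d$len, d$surface), , drop = FALSE])
  list(by_first = by_first)
}

span_frame <- function(report_id, pos_b = integer(), pos_e = integer(),
                       etype = character(), family = NULL) {
  d <- data.frame(report_id = rep_len(as.character(report_id),
                                      length(pos_b)),
                  pos_b = as.integer(pos_b), pos_e = as.integer(pos_e),
                  etype = as.character(etype), stringsAsFactors = FALSE)
  if (!is.null(family)) d$family <- as.character(family)
  d
}

#' Annotate a whole corpus of paragraphs
#' @param paragraphs List of `echo_paragraph` objects.
#' @param lex An `echo_lexicon`.
#' @return A single span data frame (rows from all reports).
#' @export
fmm_annotate_corpus <- function(paragraphs, lex) {
  out <- lapply(paragraphs, fmm_annotate, lex = lex)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) span_frame(character()) else res
}

#' Convert spans to a BIO tag sequence and back
#'
#' `spans_to_bio()` tags the first character of each span `B-<type>` and the
#' rest `I-<type>`; all other characters are `O`.  `bio_to_spans()` inverts
#' this, and also accepts ill-formed model output: an `I-t` whose predecessor
#' is neither `B-t` nor `I-t` is repaired to `B-t` (opening a new span), so
#' every predicted character region yields a span for strict evaluation.
#'
#' @param paragraph An `echo_paragraph` or plain string.
#' @param spans Span data frame valid for the paragraph (disjoint intervals
#'   within `[0, n]`).
#' @param report_id Report id when `paragraph` is a plain string.
#' @return `spans_to_bio()` returns a list of class `tag_sequence` with
#'   `report_id`, `chars` and parallel `tags`; `bio_to_spans()` returns a
#'   span data frame.
#' @export
spans_to_bio <- function(paragraph, spans, report_id = "") {
  if (inherits(paragraph, "echo_paragraph")) {
    text <- paragraph$text
    report_id <- paragraph$report_id
  } else text <- nfc(as.character(paragraph))
  chars <- chars_of(text)
  n <- length(chars)
  tags <- rep("O", n)
  if (nrow(spans)) {
    spans <- spans[order(spans$pos_b), , drop = FALSE]
    if (any(spans$pos_b < 0L) || any(spans$pos_e > n) ||
        any(spans$pos_b >= spans$pos_e)) {
      stop("span outside paragraph bounds or empty (report ", report_id, ")")
    }
    if (nrow(spans) > 1L &&
        any(spans$pos_b[-1L] < spans$pos_e[-nrow(spans)])) {
      stop("overlapping spans (report ", report_id, ")")
    }
    for (r in seq_len(nrow(spans))) {
      b <- spans$pos_b[r] + 1L; e <- spans$pos_e[r]
      tags[b] <- paste0("B-", spans$etype[r])
      if (e > b) tags[(b + 1L):e] <- paste0("I-", spans$etype[r])
    }
  }
  structure(list(report_id = report_id, chars = chars, tags = tags),
            class = "tag_sequence")
}

#' @param tag_sequence A `tag_sequence` (or list with `report_id`, `chars`,
#'   `tags`).
#' @param scheme Label scheme whose tag set validates the input (default
#'   [label_scheme()]).
#' @rdname spans_to_bio
#' @export
bio_to_spans <- function(tag_sequence, scheme = label_scheme()) {
  tags <- tag_sequence$tags
  if (length(tags) != length(tag_sequence$chars)) {
    stop("chars and tags must be parallel")
  }
  unknown <- setdiff(unique(tags), scheme$tags)
  if (length(unknown)) {
    stop("unknown tag label(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(tags)
  pos_b <- integer(); pos_e <- integer(); etype <- character()
  cur_type <- NULL; cur_start <- NA_integer_
  close_span <- function(end_excl) {
    pos_b <<- c(pos_b, cur_start); pos_e <<- c(pos_e, end_excl)
    etype <<- c(etype, cur_type); cur_type <<- NULL
  }
  for (i in seq_len(n)) {
    t <- tags[i]
    if (t == "O") {
      if (!is.null(cur_type)) close_span(i - 1L)
      next
    }
    kind <- substr(t, 1L, 1L)
    ty <- substr(t, 3L, nchar(t))
    if (kind == "B" || is.null(cur_type) || cur_type != ty) {
      # B- opens a span; an I-t without a legal predecessor is promoted to B-t
      if (!is.null(cur_type)) close_span(i - 1L)
      cur_type <- ty; cur_start <- i - 1L
    }
    # I-t continuing a span of the same type: nothing to do
  }
  if (!is.null(cur_type)) close_span(n)
  span_frame(tag_sequence$report_id, pos_b, pos_e, etype)
}

#' Write / read tag sequences in CoNLL two-column format
#'
#' One `char<TAB>tag` pair per line, a blank line between sequences, and a
#' `# id = <report_id>` comment heading each sequence so spans keep their
#' report of origin.  `read_conll(write_conll(x))` is the identity.
#'
#' @param tag_sequences List of `tag_sequence` objects.
#' @param path File path.
#' @return `read_conll()` returns a list of `tag_sequence` objects.
#' @export
write_conll <- function(tag_sequences, path) {
  blocks <- lapply(tag_sequences, function(ts) {
    c(paste0("# id = ", ts$report_id),
      if (length(ts$chars)) paste0(ts$chars, "\t", ts$tags), "")
  })
  write_utf8_lines(unlist(blocks, use.names = FALSE), path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- read_utf8_lines(path)
  out <- list()
  cur_id <- ""; cur_chars <- character(); cur_tags <- character()
  open <- FALSE
  flush_seq <- function() {
    out[[length(out) + 1L]] <<- structure(
      list(report_id = cur_id, chars = cur_chars, tags = cur_tags),
      class = "tag_sequence")
    cur_id <<- ""; cur_chars <<- character(); cur_tags <<- character()
    open <<- FALSE
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) {
      if (open) flush_seq()
      next
    }
    if (startsWith(line, "# id = ")) {
      if (open) flush_seq()
      cur_id <- substr(line, 8L, nchar(line))
      open <- TRUE
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed CoNLL line ", i, " in ", path,
           " (expected char<TAB>tag)")
    }
    open <- TRUE
    cur_chars <- c(cur_chars, parts[1L]); cur_tags <- c(cur_tags, parts[2L])
  }
  if (open) flush_seq()
  out
}

#' Write / read span files
#'
#' TSV with columns `report_id`, `pos_b`, `pos_e`, `etype` (plus `family`
#' when present), one quadruple per row, with a header line.
#' @param spans Span data frame.
#' @param path File path.
#' @return `read_spans()` returns a span data frame.
#' @export
write_spans <- function(spans, path) {
  cols <- intersect(c("report_id", "pos_b", "pos_e", "etype", "family"),
                    names(spans))
  header <- paste(cols, collapse = "\t")
  rows <- if (nrow(spans)) {
    do.call(paste, c(lapply(cols, function(cl) as.character(spans[[cl]])),
                     sep = "\t"))
  } else character()
  write_utf8_lines(c(header, rows), path)
}

#' @rdname write_spans
#' @export
read_spans <- function(path) {
  lines <- read_utf8_lines(path)
  if (!length(lines)) return(span_frame(character()))
  cols <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    d <- span_frame(character())
    if ("family" %in% cols) d$family <- character()
    return(d)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(cols))) stop("ragged span file: ", path)
  d <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(d) <- cols
  d$pos_b <- as.integer(d$pos_b); d$pos_e <- as.integer(d$pos_e)
  d
}

#' Extract the surface text of spans from their paragraphs
#' @param spans Span data frame.
#' @param paragraphs Named list of `echo_paragraph` objects (names = ids).
#' @return Character vector of span surfaces.
#' @export
span_surfaces <- function(spans, paragraphs) {
  if (!nrow(spans)) return(character())
  vapply(seq_len(nrow(spans)), function(r) {
    p <- paragraphs[[spans$report_id[r]]]
    if (is.null(p)) stop("no paragraph for report ", spans$report_id[r])
    if (spans$pos_e[r] > p$n || spans$pos_b[r] < 0L) {
      stop("span outside paragraph bounds (report ", spans$report_id[r], ")")
    }
    substr0(p$text, spans$pos_b[r], spans$pos_e[r])
  }, "")
}
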