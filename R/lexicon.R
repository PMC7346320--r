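#' Evidence-phrase lexicons
#'
#' The lexicon is the weak-supervision signal of the pipeline: a mapping from
#' Chinese surface strings to entity-type codes, with provenance recording how
#' each phrase entered the vocabulary (`seed` = summarized by ultrasound
#' clinicians, `harvested` = matched by regex expansion, `manual` = curated
#' additions such as the potential-evidence phrases and the compound
#' aortic+mitral phrase).  All surfaces are NFC-normalized on construction so
#' that CJK compatibility variants cannot silently break exact matching.
#'
#' @param entries Data frame with columns `surface`, `etype`, `provenance`.
#' @param registry Entity-type registry used to validate `etype` codes
#'   (default [all_entity_types()]).
#' @return An object of class `echo_lexicon`: a list with `entries` (the
#'   validated data frame) and `max_len` (character length of the longest
#'   surface; 0 for an empty lexicon).
#' @examples
#' lex <- lexicon(data.frame(surface = "二尖瓣狭窄",
#'                           etype = "mitral_stenosis", provenance = "seed"))
#' lex$max_len
#' @export
lexicon <- function(entries, registry = all_entity_types()) {
  if (missing(entries) || is.null(entries)) {
    entries <- data.frame(surface = character(), etype = character(),
                          provenance = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(entries),
            all(c("surface", "etype", "provenance") %in% names(entries)))
  entries <- entries[, c("surface", "etype", "provenance")]
  entries$surface <- stringi::stri_trans_nfc(enc2utf8(as.character(entries$surface)))
  entries$etype <- as.character(entries$etype)
  entries$provenance <- as.character(entries$provenance)
  if (nrow(entries)) {
    if (any(!nzchar(entries$surface))) stop("empty surface string in lexicon")
    if (any(grepl("[\r\n]", entries$surface))) {
      stop("lexicon surfaces must not contain line breaks")
    }
    dup <- duplicated(entries$surface)
    if (any(dup)) {
      confl <- entries$surface[dup]
      stop("duplicate lexicon surface(s): ", paste(unique(confl), collapse = ", "))
    }
    bad <- setdiff(unique(entries$etype), registry$code)
    if (length(bad)) {
      stop("unknown entity-type code(s): ", paste(bad, collapse = ", "))
    }
    badp <- setdiff(unique(entries$provenance), c("seed", "harvested", "manual"))
    if (length(badp)) {
      stop("unknown provenance value(s): ", paste(badp, collapse = ", "))
    }
  }
  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         max_len = if (nrow(entries)) max(nchar(entries$surface)) else 0L),
    class = "echo_lexicon"
  )
}

#' @export
print.echo_lexicon <- function(x, ...) {
  cat("echo_lexicon: ", nrow(x$entries), " phrases, ",
      length(unique(x$entries$etype)), " entity types, max surface length ",
      x$max_len, "\n", sep = "")
  invisible(x)
}

#' The packaged clinician lexicon
#'
#' `default_lexicon()` loads the lexicon shipped with the package: the 27
#' clinician-seed phrases covering 20 evidence classes, the printed
#' regex-harvested surface forms, the three potential-evidence phrases, the
#' compound aortic+mitral calcification phrase, and the left-ventricular
#' mural-thrombus abbreviation.  `annotation_lexicon()` restricts a lexicon to
#' the entity types tagged by the sequence model (default: the 11-type
#' modeling registry), which is the dictionary actually used for forward
#' maximum matching.
#'
#' @param lex An `echo_lexicon` (default the packaged one).
#' @param types Registry (or character vector of codes) to keep.
#' @return An `echo_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_table1.tsv", package = "echoNER",
                           mustWork = TRUE))
}

#' @rdname default_lexicon
#' @export
annotation_lexicon <- function(lex = default_lexicon(), types = entity_types()) {
  codes <- if (is.data.frame(types)) types$code else as.character(types)
  lexicon(lex$entries[lex$entries$etype %in% codes, , drop = FALSE],
          registry = data.frame(code = codes))
}

#' Read / write a lexicon TSV
#'
#' File format: `surface<TAB>etype<TAB>provenance`, UTF-8, one entry per
#' line, `#` comment lines allowed.  Writing then reading reproduces the
#' entry set; duplicate surfaces (in particular a surface mapped to two
#' types) are rejected with the offending line numbers.
#'
#' @param path File path.
#' @param registry Registry validating the `etype` column.
#' @param lex An `echo_lexicon` to write.
#' @return `read_lexicon()` returns an `echo_lexicon`; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path, registry = all_entity_types()) {
  lines <- read_utf8_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(lexicon(NULL, registry = registry))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    stop("malformed lexicon line(s) (expected 3 tab-separated fields) at line ",
         paste(keep[nfield != 3L], collapse = ", "), " of ", path)
  }
  entries <- data.frame(
    surface = vapply(parts, `[[`, "", 1L),
    etype = vapply(parts, `[[`, "", 2L),
    provenance = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(stringi::stri_trans_nfc(entries$surface))
  if (any(dup)) {
    stop("duplicate surface(s) in ", path, " at line ",
         paste(keep[dup], collapse = ", "))
  }
  tryCatch(
    lexicon(entries, registry = registry),
    error = function(e) stop("invalid lexicon file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "echo_lexicon"))
  e <- lex$entries
  write_utf8_lines(sprintf("%s\t%s\t%s", e$surface, e$etype, e$provenance), path)
  invisible(path)
}

#' Merge new entries into a lexicon
#'
#' Entries whose surface is already present are dropped (the existing entry
#' wins), so merging freshly harvested phrases into a seed lexicon is
#' idempotent.
#'
#' @param lex An `echo_lexicon`.
#' @param entries Data frame of candidate entries (`surface`, `etype`,
#'   `provenance`).
#' @param registry Registry validating type codes.
#' @return The merged `echo_lexicon`.
#' @export
merge_lexicon <- function(lex, entries, registry = all_entity_types()) {
  stopifnot(inherits(lex, "echo_lexicon"))
  if (is.null(entries) || !nrow(entries)) return(lex)
  entries$surface <- stringi::stri_trans_nfc(enc2utf8(as.character(entries$surface)))
  new <- entries[!(entries$surface %in% lex$entries$surface), , drop = FALSE]
  lexicon(rbind(lex$entries, new[, c("surface", "etype", "provenance")]),
          registry = registry)
}

#' Harvest extended phrases from a corpus by regular expressions
#'
#' Applies each harvest pattern to each corpus line and collects the full,
#' leftmost non-overlapping matches as candidate lexicon entries with
#' provenance `"harvested"`.  Pattern wildcards use the CJK character class
#' (code points U+4E00 to U+9FA5; backslash-u escapes in pattern files are
#' translated to the PCRE `\\x` form), so phrases containing ASCII
#' characters such as `-` are deliberately *not* harvested — extending a
#' lexicon past that limitation is the sequence model's job.
#'
#' @param patterns Data frame with columns `pattern` and `etype` (see
#'   [read_patterns()]).
#' @param corpus_lines Character vector of text lines (may be empty).
#' @return Data frame of deduplicated entries (`surface`, `etype`,
#'   `provenance = "harvested"`), in first-occurrence order.  A pattern that
#'   does not compile, or two patterns of different types harvesting the same
#'   surface, is an error.
#' @examples
#' pats <- data.frame(
#'   pattern = "二尖瓣[\\u4e00-\\u9fa5]*狭窄",
#'   etype = "mitral_stenosis")
#' harvest(pats, "二尖瓣轻度狭窄。")
#' @export
harvest <- function(patterns, corpus_lines) {
  stopifnot(is.data.frame(patterns),
            all(c("pattern", "etype") %in% names(patterns)))
  corpus_lines <- stringi::stri_trans_nfc(enc2utf8(as.character(corpus_lines)))
  out_surface <- character()
  out_etype <- character()
  for (p in seq_len(nrow(patterns))) {
    rx <- compile_harvest_pattern(patterns$pattern[p])
    if (!length(corpus_lines)) next
    m <- regmatches(corpus_lines, gregexpr(rx, corpus_lines, perl = TRUE))
    hits <- unlist(m, use.names = FALSE)
    if (length(hits)) {
      out_surface <- c(out_surface, hits)
      out_etype <- c(out_etype, rep(patterns$etype[p], length(hits)))
    }
  }
  keep <- !duplicated(out_surface)
  res <- data.frame(surface = out_surface[keep], etype = out_etype[keep],
                    provenance = rep("harvested", sum(keep)),
                    stringsAsFactors = FALSE)
  confl <- tapply(out_etype, out_surface, function(x) length(unique(x)))
  if (length(confl) && any(confl > 1L)) {
    stop("surface(s) harvested under conflicting types: ",
         paste(names(confl)[confl > 1L], collapse = ", "))
  }
  rownames(res) <- NULL
  res
}

# Translate the \uXXXX escape convention of pattern files into PCRE \x{....}
# and verify that the resulting regex compiles.
compile_harvest_pattern <- function(pattern) {
  rx <- gsub("\\\\u([0-9a-fA-F]{4})", "\\\\x{\\1}", enc2utf8(pattern))
  ok <- tryCatch({ regexpr(rx, "", perl = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("harvest pattern does not compile: ", pattern)
  rx
}

#' Read a harvest-pattern file
#'
#' Format: `pattern<TAB>etype`, UTF-8, `#` comments allowed.  Every pattern
#' is compiled on load; a non-compiling pattern is a configuration error
#' naming the pattern.
#'
#' @param path File path.
#' @param registry Registry validating type codes.
#' @return Data frame with columns `pattern`, `etype`.
#' @export
read_patterns <- function(path, registry = all_entity_types()) {
  lines <- read_utf8_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed pattern line(s) at line ",
         paste(keep[lengths(parts) != 2L], collapse = ", "), " of ", path)
  }
  pats <- data.frame(pattern = vapply(parts, `[[`, "", 1L),
                     etype = vapply(parts, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
  bad <- setdiff(unique(pats$etype), registry$code)
  if (length(bad)) stop("unknown entity-type code(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  for (p in pats$pattern) compile_harvest_pattern(p)
  pats
}

#' Default harvest patterns shipped with the package
#' @return Data frame with columns `pattern`, `etype`.
#' @export
default_patterns <- function() {
  read_patterns(system.file("extdata", "harvest_patterns.tsv",
                            package = "echoNER", mustWork = TRUE))
}

#' Tabulate a lexicon
#'
#' Counts entries by entity type, provenance, or entity-type category; the
#' counts always sum to the number of entries.
#'
#' @param lex An `echo_lexicon`.
#' @param by One of `"etype"`, `"provenance"`, `"category"`.
#' @param registry Registry supplying the `category` of each type code.
#' @return Data frame with columns `key` and `n`, sorted by decreasing count.
#' @export
count_lexicon <- function(lex, by = c("etype", "provenance", "category"),
                          registry = all_entity_types()) {
  stopifnot(inherits(lex, "echo_lexicon"))
  by <- match.arg(by)
  e <- lex$entries
  key <- switch(by,
    etype = e$etype,
    provenance = e$provenance,
    category = registry$category[match(e$etype, registry$code)]
  )
  if (!length(key)) {
    return(data.frame(key = character(), n = integer(), stringsAsFactors = FALSE))
  }
  tab <- sort(table(key), decreasing = TRUE)
  data.frame(key = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
}
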