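#' Read and write six-field echocardiograph report records
#'
#' Reports are exchanged as UTF-8 line-delimited JSON: one object per line
#' with fields `report_id`, `patient_id`, `exam_time`, `exam_item`,
#' `exam_category`, `description` (array of ultrasound-description lines) and
#' `conclusion` (array of ultrasound-conclusion lines).  Line arrays may be
#' empty but must be present; report ids must be unique within a file.
#'
#' @param path File path.
#' @param reports A list of report records (as returned by `read_reports()`
#'   or [generate_corpus()]).
#' @return `read_reports()` returns a list of report records (each a list
#'   with the seven fields above, class `echo_report`); `write_reports()`
#'   returns `path` invisibly.
#' @export
read_reports <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  reports <- vector("list", length(lines))
  required <- c("report_id", "patient_id", "exam_time", "exam_item",
                "exam_category", "description", "conclusion")
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("record ", i, ": invalid JSON (",
                                             conditionMessage(e), ")", call. = FALSE))
    missing_f <- setdiff(required, names(rec))
    if (length(missing_f)) {
      stop("record ", i, ": missing required field(s) ",
           paste(missing_f, collapse = ", "))
    }
    reports[[i]] <- echo_report(
      report_id = rec$report_id, patient_id = rec$patient_id,
      exam_time = rec$exam_time, exam_item = rec$exam_item,
      exam_category = rec$exam_category,
      description = as.character(unlist(rec$description)),
      conclusion = as.character(unlist(rec$conclusion))
    )
  }
  ids <- vapply(reports, `[[`, "", "report_id")
  if (anyDuplicated(ids)) {
    stop("duplicate report_id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  }
  reports
}

#' @rdname read_reports
#' @export
write_reports <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(
      report_id = jsonlite::unbox(r$report_id),
      patient_id = jsonlite::unbox(r$patient_id),
      exam_time = jsonlite::unbox(r$exam_time),
      exam_item = jsonlite::unbox(r$exam_item),
      exam_category = jsonlite::unbox(r$exam_category),
      description = as.character(r$description),
      conclusion = as.character(r$conclusion)
    ))
  }, "")
  write_utf8_lines(lines, path)
}

#' Construct a report record
#'
#' @param report_id,patient_id,exam_time,exam_item,exam_category Scalar
#'   strings; `report_id` must be non-empty.
#' @param description,conclusion Character vectors of source lines (may be
#'   empty, not NULL).
#' @return A list of class `echo_report`.
#' @export
echo_report <- function(report_id, patient_id = "", exam_time = "",
                        exam_item = "", exam_category = "",
                        description = character(), conclusion = character()) {
  report_id <- as.character(report_id)
  if (length(report_id) != 1L || !nzchar(report_id)) {
    stop("report_id must be a non-empty string")
  }
  stopifnot(!is.null(description), !is.null(conclusion))
  structure(list(
    report_id = report_id,
    patient_id = as.character(patient_id), exam_time = as.character(exam_time),
    exam_item = as.character(exam_item), exam_category = as.character(exam_category),
    description = enc2utf8(as.character(description)),
    conclusion = enc2utf8(as.character(conclusion))
  ), class = "echo_report")
}

# Normalize one source line: NFC, strip spaces (ASCII space, tab, ideographic
# space), lowercase ASCII letters.
normalize_line <- function(line) {
  x <- nfc(line)
  x <- gsub("[ \t 　]+", "", x, perl = TRUE)
  tolower(x)
}

#' Normalize a report into a single annotation-ready paragraph
#'
#' Reproduces the corpus preprocessing: each line is NFC-normalized, spaces
#' are removed and ASCII letters lowercased; the description lines are
#' concatenated in order (they carry their own terminal punctuation); the
#' conclusion lines are joined into one sentence with a comma delimiter
#' (full-width `，` by default) and appended after the description.  The
#' returned paragraph records, for every retained source line, its half-open
#' 0-based character interval in the normalized text, so spans can be traced
#' back to the originating line.
#'
#' @param report An `echo_report`.
#' @param conclusion_sep Delimiter inserted between conclusion lines.
#' @param description_sep Delimiter inserted between description lines
#'   (default none).
#' @return A list of class `echo_paragraph`: `report_id`, `text`, `n`
#'   (character count), and `offsets`, a data frame with columns `section`
#'   (`"description"`/`"conclusion"`), `line` (1-based source line index),
#'   `start`, `end` (0-based half-open interval in `text`).
#' @examples
#' r <- echo_report("r1", description = "EF 60%",
#'                  conclusion = c("主动脉瓣钙化", "二尖瓣狭窄"))
#' normalize_report(r)$text
#' @export
normalize_report <- function(report, conclusion_sep = "，",
                             description_sep = "") {
  stopifnot(inherits(report, "echo_report"))
  sections <- list(description = report$description,
                   conclusion = report$conclusion)
  seps <- c(description = description_sep, conclusion = conclusion_sep)
  text_parts <- character()
  off <- list()
  pos <- 0L
  for (sec in names(sections)) {
    lines <- sections[[sec]]
    sep_n <- nchar(seps[[sec]])
    for (j in seq_along(lines)) {
      norm <- normalize_line(lines[[j]])
      if (j > 1L && sep_n > 0L) {
        text_parts <- c(text_parts, seps[[sec]])
        pos <- pos + sep_n
      }
      len <- nchar(norm)
      off[[length(off) + 1L]] <- data.frame(
        section = sec, line = j, start = pos, end = pos + len,
        stringsAsFactors = FALSE)
      text_parts <- c(text_parts, norm)
      pos <- pos + len
    }
  }
  text <- paste0(text_parts, collapse = "")
  offsets <- if (length(off)) do.call(rbind, off) else
    data.frame(section = character(), line = integer(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  structure(list(report_id = report$report_id, text = text,
                 n = nchar(text), offsets = offsets),
            class = "echo_paragraph")
}

#' @export
print.echo_paragraph <- function(x, ...) {
  cat("echo_paragraph [", x$report_id, "]: ", x$n, " chars\n", sep = "")
  invisible(x)
}

#' Normalize a list of reports
#' @param reports List of `echo_report` records.
#' @param ... Passed to [normalize_report()].
#' @return Named list of `echo_paragraph` objects (names = report ids).
#' @export
normalize_corpus <- function(reports, ...) {
  out <- lapply(reports, normalize_report, ...)
  names(out) <- vapply(out, `[[`, "", "report_id")
  out
}

#' Write normalized paragraphs as a plain-text corpus file
#'
#' One paragraph per line, the format consumed by [train_char_vectors()].
#' @param paragraphs List of `echo_paragraph` objects.
#' @param path File path.
#' @export
write_paragraphs <- function(paragraphs, path) {
  write_utf8_lines(vapply(paragraphs, `[[`, "", "text"), path)
}

#' Split report ids into training and test partitions
#'
#' A uniform random permutation under a fixed seed, cut at
#' `floor(N * train_fraction)`; the partition is disjoint, exhaustive and
#' reproducible.  Splitting 4188 report ids at the 8:2 ratio yields the
#' 3350/838 partition used for model construction and validation.
#'
#' @param report_ids Character vector of ids.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @examples
#' sizes <- lengths(split_corpus(sprintf("r%04d", 1:4188), 0.8, seed = 1))
#' sizes  # 3350, 838
#' @export
split_corpus <- function(report_ids, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  report_ids <- as.character(report_ids)
  n <- length(report_ids)
  if (n == 0L) return(list(train = character(), test = character()))
  n_train <- floor(n * train_fraction)
  perm <- with_seed(seed, sample.int(n))
  list(train = report_ids[perm[seq_len(n_train)]],
       test = report_ids[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
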