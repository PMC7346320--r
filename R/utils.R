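# Internal helpers shared across modules.  All file IO in the package is
# UTF-8 regardless of locale, and all text is NFC-normalized at the border.

read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  enc2utf8(lines)
}

write_utf8_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(enc2utf8(as.character(lines)), con, useBytes = TRUE)
  } else {
    # create/truncate an empty file
    writeLines(character(), con, useBytes = TRUE)
  }
  invisible(path)
}

# Split a UTF-8 string into code-point characters (0 chars for "").
chars_of <- function(x) {
  if (!nzchar(x)) return(character())
  strsplit(enc2utf8(x), "", fixed = FALSE)[[1]]
}

# 0-based half-open substring of a UTF-8 string.
substr0 <- function(x, pos_b, pos_e) {
  substr(x, pos_b + 1L, pos_e)
}

nfc <- function(x) stringi::stri_trans_nfc(enc2utf8(x))
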