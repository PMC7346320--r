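#' Character vocabulary of a paragraph corpus
#'
#' Distinct characters of the corpus plus the two reserved tokens `<pad>`
#' (index 1) and `<unk>` (index 2); remaining characters follow in code-point
#' order so the vocabulary is reproducible.
#'
#' @param corpus_paragraphs Character vector of paragraph texts (or list of
#'   `echo_paragraph` objects).
#' @return A list of class `char_vocab`: `chars` (character vector including
#'   the reserved tokens), `index` (named integer vector mapping character to
#'   index), `pad = 1L`, `unk = 2L`.
#' @export
char_vocab <- function(corpus_paragraphs) {
  texts <- paragraph_texts(corpus_paragraphs)
  uniq <- sort(unique(unlist(lapply(texts, chars_of), use.names = FALSE)),
               method = "radix")
  chars <- c("<pad>", "<unk>", uniq)
  index <- seq_along(chars)
  names(index) <- chars
  structure(list(chars = chars, index = index, pad = 1L, unk = 2L),
            class = "char_vocab")
}

paragraph_texts <- function(x) {
  if (is.character(x)) return(nfc(x))
  vapply(x, function(p) if (inherits(p, "echo_paragraph")) p$text else nfc(p), "")
}

#' Map characters to vocabulary indices
#' @param chars Character vector of single characters.
#' @param vocab A `char_vocab`.
#' @return Integer indices; characters absent from the vocabulary map to the
#'   `<unk>` index.
#' @export
vocab_lookup <- function(chars, vocab) {
  idx <- vocab$index[chars]
  idx[is.na(idx)] <- vocab$unk
  unname(idx)
}

#' Pre-train distributional character vectors
#'
#' Learns `dim`-dimensional character vectors from windowed co-occurrence
#' statistics of the paragraph corpus: symmetric counts within `window`
#' characters on each side are converted to positive pointwise mutual
#' information and factorized by a truncated SVD, the standard count-based
#' counterpart of skip-gram training (Levy-Goldberg factorization).  Defaults
#' are the pipeline's standard setting: 100-dimensional vectors, window 5.  The
#' procedure is fully deterministic: singular-vector signs are fixed so
#' retraining reproduces the identical table (the `seed` argument is accepted
#' for interface uniformity).  The `<unk>` vector is the mean of all trained
#' vectors; `<pad>` is the zero vector.
#'
#' @param corpus_paragraphs Character vector of paragraph texts (or list of
#'   `echo_paragraph`s); must be non-empty.
#' @param dim Vector dimension (default 100).
#' @param window Context-window half-width in characters (default 5).
#' @param seed Unused (training is deterministic); kept so callers can treat
#'   all trainers uniformly.
#' @return A list of class `char_embeddings`: `vocab` (a [char_vocab()]) and
#'   `vectors`, a `length(vocab$chars) x dim` numeric matrix with rownames.
#' @export
train_char_vectors <- function(corpus_paragraphs, dim = 100L, window = 5L,
                               seed = 1L) {
  texts <- paragraph_texts(corpus_paragraphs)
  texts <- texts[nzchar(texts)]
  if (!length(texts)) stop("embedding corpus is empty")
  stopifnot(dim >= 1L, window >= 1L)
  vocab <- char_vocab(texts)
  nv <- length(vocab$chars)
  pair_idx <- vector("list", length(texts))
  for (t in seq_along(texts)) {
    ids <- vocab_lookup(chars_of(texts[[t]]), vocab)
    n <- length(ids)
    px <- integer()
    for (off in seq_len(min(window, n - 1L))) {
      i <- ids[seq_len(n - off)]
      j <- ids[seq.int(off + 1L, n)]
      # linear indices of both orientations (symmetric counts)
      px <- c(px, (j - 1L) * nv + i, (i - 1L) * nv + j)
    }
    pair_idx[[t]] <- px
  }
  counts <- matrix(as.numeric(tabulate(unlist(pair_idx, use.names = FALSE),
                                       nbins = nv * nv)), nv, nv)
  total <- sum(counts)
  if (total == 0) {
    vectors <- matrix(0, nv, dim)
  } else {
    row_s <- rowSums(counts)
    with_pmi <- log(counts * total) -
      log(outer(row_s, row_s))            # log((c_ij N)/(r_i r_j))
    with_pmi[!is.finite(with_pmi)] <- 0
    ppmi <- pmax(with_pmi, 0)
    sv <- svd(ppmi)
    d_use <- min(dim, length(sv$d))
    vecs <- sv$u[, seq_len(d_use), drop = FALSE] %*%
      diag(sqrt(sv$d[seq_len(d_use)]), d_use)
    # deterministic sign: largest-|.| component of each column made positive
    for (cc in seq_len(d_use)) {
      piv <- which.max(abs(vecs[, cc]))
      if (vecs[piv, cc] < 0) vecs[, cc] <- -vecs[, cc]
    }
    vectors <- matrix(0, nv, dim)
    vectors[, seq_len(d_use)] <- vecs
  }
  trained <- setdiff(seq_len(nv), c(vocab$pad, vocab$unk))
  vectors[vocab$unk, ] <- if (length(trained))
    colMeans(vectors[trained, , drop = FALSE]) else 0
  vectors[vocab$pad, ] <- 0
  rownames(vectors) <- vocab$chars
  structure(list(vocab = vocab, vectors = vectors), class = "char_embeddings")
}

#' @export
print.char_embeddings <- function(x, ...) {
  cat("char_embeddings: ", nrow(x$vectors), " characters x ", ncol(x$vectors),
      " dims\n", sep = "")
  invisible(x)
}

#' Cosine similarity between two characters' vectors
#' @param emb A `char_embeddings`.
#' @param a,b Single characters.
#' @return Numeric scalar in `[-1, 1]` (0 if either vector is all-zero).
#' @export
char_cosine <- function(emb, a, b) {
  va <- emb$vectors[vocab_lookup(a, emb$vocab), ]
  vb <- emb$vectors[vocab_lookup(b, emb$vocab), ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Read / write embeddings in the word-vector text format
#'
#' First line `vocab_size dim`, then one `char v1 ... v_dim` line per
#' character (space-separated, UTF-8).
#' @param emb A `char_embeddings`.
#' @param path File path.
#' @return `read_embeddings()` returns a `char_embeddings`.
#' @export
write_embeddings <- function(emb, path) {
  v <- emb$vectors
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.9g", v[i, ])), collapse = " ")
  }, "")
  write_utf8_lines(c(paste(nrow(v), ncol(v)), body), path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- read_utf8_lines(path)
  if (!length(lines)) stop("empty embedding file: ", path)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1]])
  nv <- hdr[1L]; dm <- hdr[2L]
  body <- lines[-1L]
  if (length(body) != nv) stop("embedding file row count mismatch: ", path)
  chars <- character(nv)
  vectors <- matrix(0, nv, dm)
  for (i in seq_len(nv)) {
    parts <- strsplit(body[i], " ", fixed = TRUE)[[1]]
    if (length(parts) != dm + 1L) stop("malformed embedding line ", i + 1L)
    chars[i] <- parts[1L]
    vectors[i, ] <- as.numeric(parts[-1L])
  }
  rownames(vectors) <- chars
  index <- seq_along(chars); names(index) <- chars
  vocab <- structure(list(chars = chars, index = index,
                          pad = match("<pad>", chars),
                          unk = match("<unk>", chars)),
                     class = "char_vocab")
  structure(list(vocab = vocab, vectors = vectors), class = "char_embeddings")
}
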