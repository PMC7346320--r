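# Independent oracles and small fixture builders shared across tests.

# Exhaustive CRF oracle: enumerate all k^n label sequences with
# crf_sequence_score and reduce by max / log-sum-exp.  Only usable for
# n <= 4, k <= 4.
enum_all_scores <- function(P, A) {
  k <- ncol(P); n <- nrow(P)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  apply(grid, 1L, function(y) crf_sequence_score(P, A, as.integer(y)))
}

enum_log_partition <- function(P, A) {
  sc <- enum_all_scores(P, A)
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

enum_max_score <- function(P, A) max(enum_all_scores(P, A))

# Brute-force forward-maximum-matching oracle: simulates the greedy
# longest-first scan by exhaustive window enumeration over a plain
# surface/etype table (no index structures).
fmm_oracle <- function(text, entries) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  max_len <- if (nrow(entries)) max(nchar(entries$surface)) else 0L
  pos_b <- integer(); pos_e <- integer(); etype <- character()
  i <- 1L
  while (i <= n) {
    adv <- 1L
    if (max_len > 0L) {
      for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
        w <- paste0(chars[i:(i + len - 1L)], collapse = "")
        hit <- which(entries$surface == w)
        if (length(hit)) {
          pos_b <- c(pos_b, i - 1L); pos_e <- c(pos_e, i - 1L + len)
          etype <- c(etype, entries$etype[hit[1L]])
          adv <- len
          break
        }
      }
    }
    i <- i + adv
  }
  data.frame(pos_b = pos_b, pos_e = pos_e, etype = etype,
             stringsAsFactors = FALSE)
}

# Random toy paragraph / lexicon pair over a small CJK alphabet.
toy_alphabet <- c("二", "尖", "瓣", "狭", "窄", "心")

random_toy_case <- function() {
  n_entries <- sample.int(6L, 1L)
  surfaces <- unique(vapply(seq_len(n_entries), function(i) {
    paste0(sample(toy_alphabet, sample.int(4L, 1L), replace = TRUE),
           collapse = "")
  }, ""))
  entries <- data.frame(surface = surfaces,
                        etype = paste0("t", seq_along(surfaces)),
                        provenance = "manual", stringsAsFactors = FALSE)
  text <- paste0(sample(toy_alphabet, sample.int(30L, 1L), replace = TRUE),
                 collapse = "")
  list(entries = entries, text = text)
}

# A tiny two-type label world for model-level tests.
tiny_scheme <- function() label_scheme(c("a", "b"))

tiny_embeddings <- function(chars, dim = 8L, seed = 1L) {
  vocab_chars <- c("<pad>", "<unk>", sort(unique(chars)))
  index <- seq_along(vocab_chars)
  names(index) <- vocab_chars
  vocab <- structure(list(chars = vocab_chars, index = index,
                          pad = 1L, unk = 2L), class = "char_vocab")
  set.seed(seed)
  vectors <- matrix(stats::rnorm(length(vocab_chars) * dim, sd = 0.3),
                    length(vocab_chars), dim,
                    dimnames = list(vocab_chars, NULL))
  vectors[1L, ] <- 0
  structure(list(vocab = vocab, vectors = vectors),
            class = "char_embeddings")
}

# Desk-scale training configuration used by end-to-end recovery tests:
# reduced hidden size and a larger step size so the recovery experiment
# fits interactive runtimes (the model architecture is unchanged).
scaled_train_config <- function(seed = 1L, epochs = 10L) {
  train_config(learning_rate = 1e-3, dropout = 0.5, hidden_units = 32L,
               epochs = epochs, batch_size = 8L, seed = seed, patience = 3L)
}

# Annotate a corpus with FMM and build per-report tag sequences.
corpus_tag_sequences <- function(paragraphs, spans) {
  seqs <- lapply(names(paragraphs), function(id) {
    spans_to_bio(paragraphs[[id]],
                 spans[spans$report_id == id, , drop = FALSE])
  })
  names(seqs) <- names(paragraphs)
  seqs
}
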