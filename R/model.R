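#' Training configuration for the BiLSTM-CRF tagger
#'
#' Defaults are the configuration this pipeline is designed around —
#' learning rate 0.0001, dropout 0.5, 100 hidden units per direction, Adam —
#' with the
#' remaining knobs (epochs, batch size, early stopping) set to conventional
#' values for a corpus of a few thousand short clinical paragraphs.
#'
#' @param learning_rate Adam learning rate, in (0, 1].
#' @param dropout Dropout probability applied to the encoder output before
#'   the emission projection (disabled at inference), in \[0, 1).
#' @param hidden_units LSTM hidden size per direction.
#' @param epochs Maximum training epochs.
#' @param batch_size Sequences per gradient step.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param patience Early-stopping patience in epochs without dev-F1
#'   improvement (ignored when no dev set is given).
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, dropout = 0.5,
                         hidden_units = 100L, epochs = 30L, batch_size = 16L,
                         seed = 1L, patience = 5L, grad_clip = 5) {
  stopifnot(learning_rate > 0, learning_rate <= 1,
            dropout >= 0, dropout < 1,
            hidden_units >= 1, epochs >= 1, batch_size >= 1, patience >= 0)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 patience = as.integer(patience), grad_clip = grad_clip),
            class = "train_config")
}

# Convert tag sequences to integer inputs for the C++ engine.
sequences_to_xy <- function(sequences, vocab, scheme) {
  xs <- vector("list", length(sequences))
  ys <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (length(s$chars) != length(s$tags)) {
      stop("sequence ", i, ": chars and tags are not parallel")
    }
    xs[[i]] <- as.integer(vocab_lookup(s$chars, vocab))
    ys[[i]] <- as.integer(tag_index(s$tags, scheme))
  }
  list(xs = xs, ys = ys)
}

init_params <- function(vocab, emb, scheme, hidden, seed) {
  D <- ncol(emb$vectors)
  V <- length(vocab$chars)
  k <- scheme$k
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  with_seed(seed, {
    E <- emb$vectors[vocab$chars, , drop = FALSE]
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1    # forget-gate bias
    list(
      E = unname(E),
      Wxf = glorot(4 * hidden, D), Whf = glorot(4 * hidden, hidden), bf = b,
      Wxb = glorot(4 * hidden, D), Whb = glorot(4 * hidden, hidden), bb = b,
      Wo = glorot(k, 2 * hidden), bo = numeric(k),
      A = matrix(stats::rnorm((k + 2)^2, sd = 0.01), k + 2, k + 2)
    )
  })
}

zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

#' Train the character-level BiLSTM-CRF tagger
#'
#' Minimizes the mean negative log-likelihood of the gold taggings
#' (`log_partition - gold_score`, both computed exactly by the forward
#' recursion) with Adam over shuffled minibatches; pretrained character
#' embeddings initialize the embedding layer and are fine-tuned.  After each
#' epoch the model is decoded on the dev set and the checkpoint with the best
#' strict micro-F1 is kept; training stops early after `patience` epochs
#' without improvement.  Everything is deterministic given `config$seed`.
#'
#' @param train_sequences List of `tag_sequence` objects (non-empty).
#' @param dev_sequences List of `tag_sequence` objects used for checkpoint
#'   selection (may be empty, in which case the final epoch is returned).
#' @param embeddings A `char_embeddings` from [train_char_vectors()] (its
#'   vocabulary becomes the model vocabulary).
#' @param config A [train_config()].
#' @param scheme A [label_scheme()]; tags outside the scheme are an error
#'   before any training happens.
#' @param verbose Print per-epoch NLL and dev F1.
#' @return A list of class `echo_tagger`: `params`, `vocab`, `scheme`,
#'   `config`, and `log` (data frame with `epoch`, `nll`, `dev_f1`).
#' @export
train_tagger <- function(train_sequences, dev_sequences = list(),
                         embeddings, config = train_config(),
                         scheme = label_scheme(), verbose = FALSE) {
  if (!length(train_sequences)) stop("empty training set")
  stopifnot(inherits(embeddings, "char_embeddings"),
            inherits(config, "train_config"))
  vocab <- embeddings$vocab
  tr <- sequences_to_xy(train_sequences, vocab, scheme)
  dv <- sequences_to_xy(dev_sequences, vocab, scheme)
  dev_gold <- if (length(dev_sequences)) {
    do.call(rbind, lapply(dev_sequences, bio_to_spans, scheme = scheme))
  } else NULL

  params <- init_params(vocab, embeddings, scheme, config$hidden_units,
                        config$seed)
  m <- zero_like(params); v <- zero_like(params); t_adam <- 0L
  best <- list(params = params, f1 = -Inf, epoch = 0L)
  bad_epochs <- 0L
  log <- data.frame(epoch = integer(), nll = numeric(), dev_f1 = numeric())

  for (epoch in seq_len(config$epochs)) {
    order <- with_seed(config$seed + epoch,
                       sample.int(length(train_sequences)))
    res <- cpp_train_epoch(params, m, v, t_adam, tr$xs, tr$ys,
                           as.integer(order), config$learning_rate,
                           config$dropout, config$batch_size,
                           config$seed * 1000L + epoch, config$grad_clip)
    params <- res$params; m <- res$m; v <- res$v; t_adam <- res$t
    dev_f1 <- NA_real_
    if (length(dev_sequences)) {
      pred <- decode_sequences(params, dv$xs, dev_sequences, scheme)
      dev_f1 <- strict_metrics(pred, dev_gold, types = scheme$types)$overall$f1
      if (dev_f1 > best$f1 + 1e-12) {
        best <- list(params = params, f1 = dev_f1, epoch = epoch)
        bad_epochs <- 0L
      } else bad_epochs <- bad_epochs + 1L
    }
    log <- rbind(log, data.frame(epoch = epoch, nll = res$nll,
                                 dev_f1 = dev_f1))
    if (verbose) {
      message(sprintf("epoch %d  nll %.4f  dev F1 %s", epoch, res$nll,
                      ifelse(is.na(dev_f1), "-", sprintf("%.4f", dev_f1))))
    }
    if (length(dev_sequences) && config$patience > 0L &&
        bad_epochs >= config$patience) break
  }
  final <- if (length(dev_sequences) && best$epoch > 0L) best$params else params
  structure(list(params = final, vocab = vocab, scheme = scheme,
                 config = config, log = log,
                 best_epoch = if (length(dev_sequences)) best$epoch else
                   nrow(log)),
            class = "echo_tagger")
}

# Viterbi-decode integer inputs and convert the tag paths to spans.
decode_sequences <- function(params, xs, sequences, scheme) {
  paths <- cpp_predict_tags(params, xs)
  spans <- lapply(seq_along(paths), function(i) {
    ts <- structure(list(report_id = sequences[[i]]$report_id,
                         chars = sequences[[i]]$chars,
                         tags = scheme$tags[paths[[i]]]),
                    class = "tag_sequence")
    bio_to_spans(ts, scheme = scheme)
  })
  res <- do.call(rbind, c(spans, list(make.row.names = FALSE)))
  if (is.null(res)) span_frame(character()) else res
}

#' @export
print.echo_tagger <- function(x, ...) {
  cat("echo_tagger: ", length(x$vocab$chars), "-char vocab, hidden ",
      x$config$hidden_units, "/direction, k = ", x$scheme$k,
      " labels; trained ", nrow(x$log), " epochs (best epoch ",
      x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Predict evidence spans with a trained tagger
#'
#' Embeds the paragraph characters (unseen characters map to `<unk>`), runs
#' the bidirectional encoder, Viterbi-decodes the CRF (dropout disabled), and
#' converts the BIO path to spans, repairing any ill-formed `I-` openings.
#'
#' @param model An `echo_tagger`.
#' @param paragraphs A single `echo_paragraph`/string or a list of them.
#' @return A span data frame (`report_id`, `pos_b`, `pos_e`, `etype`).
#' @export
predict_spans <- function(model, paragraphs) {
  stopifnot(inherits(model, "echo_tagger"))
  if (inherits(paragraphs, "echo_paragraph") || is.character(paragraphs)) {
    paragraphs <- list(paragraphs)
  }
  seqs <- lapply(seq_along(paragraphs), function(i) {
    p <- paragraphs[[i]]
    if (inherits(p, "echo_paragraph")) {
      list(report_id = p$report_id, chars = chars_of(p$text))
    } else {
      list(report_id = if (!is.null(names(paragraphs)))
        names(paragraphs)[i] else as.character(i),
        chars = chars_of(nfc(p)))
    }
  })
  xs <- lapply(seqs, function(s) as.integer(vocab_lookup(s$chars, model$vocab)))
  decode_sequences(model$params, xs, seqs, model$scheme)
}

#' Emission matrix of a trained tagger for one paragraph
#'
#' Exposes the `n x k` encoder scores feeding the CRF, mainly so decoding can
#' be cross-checked against the reference [crf_viterbi()] implementation.
#' @param model An `echo_tagger`.
#' @param paragraph An `echo_paragraph` or string.
#' @return Numeric `n x k` matrix.
#' @export
tagger_emissions <- function(model, paragraph) {
  text <- if (inherits(paragraph, "echo_paragraph")) paragraph$text else
    nfc(paragraph)
  x <- as.integer(vocab_lookup(chars_of(text), model$vocab))
  cpp_emissions(model$params, x)
}

#' Save / load a tagger checkpoint
#'
#' The checkpoint is a single RDS file holding the parameter matrices, the
#' character vocabulary, the label scheme and the training configuration;
#' loading restores a model that decodes identically.
#' @param model An `echo_tagger`.
#' @param path File path.
#' @return `load_tagger()` returns the `echo_tagger`.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "echo_tagger"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("params", "vocab", "scheme") %in% names(obj)))
  class(obj$scheme) <- "label_scheme"
  class(obj$vocab) <- "char_vocab"
  structure(obj, class = "echo_tagger")
}
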