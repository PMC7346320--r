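#' Pipeline configuration
#'
#' Bundles the stage settings of the end-to-end run: the synthetic-corpus
#' generator, the train/test split, and the tagger training configuration.
#' Accepts either nested config objects or plain lists of overrides (handy
#' when reading YAML).
#'
#' @param generator [generator_config()] or list of overrides.
#' @param train [train_config()] or list of overrides.
#' @param split_fraction Training fraction of the corpus split (default 0.8).
#' @param dev_fraction Fraction of the training portion held out for
#'   checkpoint selection.
#' @param n_challenge Challenge reports appended by [inject_error_cases()].
#' @param seed Master seed for splitting and generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            train = train_config(),
                            split_fraction = 0.8, dev_fraction = 0.1,
                            n_challenge = 0L, seed = 1L) {
  if (!inherits(generator, "generator_config")) {
    generator <- do.call(generator_config, as.list(generator))
  }
  if (!inherits(train, "train_config")) {
    train <- do.call(train_config, as.list(train))
  }
  stopifnot(split_fraction > 0, split_fraction < 1,
            dev_fraction >= 0, dev_fraction < 1)
  structure(list(generator = generator, train = train,
                 split_fraction = split_fraction,
                 dev_fraction = dev_fraction,
                 n_challenge = as.integer(n_challenge),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `generator`, `train`, `split_fraction`, `dev_fraction`,
#' `n_challenge`, `seed`; each nested block holds the fields of the
#' corresponding config constructor.
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
    c("generator", "train", "split_fraction", "dev_fraction",
      "n_challenge", "seed"))])
}

#' Run the full weak-supervision pipeline
#'
#' Executes, in order: corpus simulation, regex harvesting over the
#' normalized paragraphs, forward-maximum-matching annotation, character
#' embedding pretraining, BiLSTM-CRF training, test-set prediction, and
#' strict evaluation.  Every stage writes its artifact into `out_dir`:
#' report records, gold and dictionary span files, CoNLL tag files,
#' embedding table, model checkpoint with per-epoch log, predicted spans,
#' metrics TSV, a per-type recall comparison of the seed dictionary /
#' extended dictionary / model against the generator gold, and a
#' novel-phrase report.  Re-running with the same configuration reproduces
#' identical span files and metrics.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if missing).
#' @param lex Annotation lexicon (default [annotation_lexicon()]).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the key artifacts: `metrics` (model vs
#'   gold), `metrics_vs_dict` (model vs dictionary annotation),
#'   `comparison`, `novel`, `model`, and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         lex = annotation_lexicon(), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reports = file.path(out_dir, "reports.ndjson"),
    gold = file.path(out_dir, "gold_spans.tsv"),
    lexicon = file.path(out_dir, "lexicon.tsv"),
    paragraphs = file.path(out_dir, "paragraphs.txt"),
    harvested = file.path(out_dir, "harvested.tsv"),
    conll_train = file.path(out_dir, "train.conll"),
    conll_test = file.path(out_dir, "test.conll"),
    embeddings = file.path(out_dir, "char_vectors.txt"),
    checkpoint = file.path(out_dir, "tagger.rds"),
    train_log = file.path(out_dir, "train_log.tsv"),
    pred = file.path(out_dir, "predicted_spans.tsv"),
    metrics = file.path(out_dir, "metrics.tsv"),
    metrics_vs_dict = file.path(out_dir, "metrics_vs_dictionary.tsv"),
    comparison = file.path(out_dir, "method_comparison.tsv"),
    novel = file.path(out_dir, "novel_phrases.tsv"),
    log = file.path(out_dir, "run.log")
  )
  log_lines <- character()
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    log_lines <<- c(log_lines, sprintf("%s\t%ss", name, dt))
    res
  }

  corpus <- stage("simulate", {
    cp <- generate_corpus(config$generator, lex = lex)
    if (config$n_challenge > 0L) {
      cp <- inject_error_cases(cp, config$n_challenge,
                               seed = config$seed + 1L)
    }
    write_reports(cp$reports, paths$reports)
    write_spans(cp$gold, paths$gold)
    write_lexicon(lex, paths$lexicon)
    cp
  })
  paragraphs <- stage("normalize", {
    pg <- normalize_corpus(corpus$reports)
    write_paragraphs(pg, paths$paragraphs)
    pg
  })
  lex_full <- stage("harvest", {
    hv <- harvest(default_patterns(),
                  vapply(paragraphs, `[[`, "", "text"))
    write_utf8_lines(c("surface\tetype\tprovenance",
                       sprintf("%s\t%s\t%s", hv$surface, hv$etype,
                               hv$provenance)), paths$harvested)
    merge_lexicon(lex, hv)
  })
  split <- split_corpus(names(paragraphs), config$split_fraction,
                        seed = config$seed)
  ann <- stage("annotate", {
    dict_spans <- fmm_annotate_corpus(paragraphs, lex_full)
    seqs <- lapply(names(paragraphs), function(id) {
      spans_to_bio(paragraphs[[id]],
                   dict_spans[dict_spans$report_id == id, , drop = FALSE])
    })
    names(seqs) <- names(paragraphs)
    n_dev <- floor(length(split$train) * config$dev_fraction)
    dev_ids <- split$train[seq_len(n_dev)]
    train_ids <- setdiff(split$train, dev_ids)
    write_conll(seqs[train_ids], paths$conll_train)
    write_conll(seqs[split$test], paths$conll_test)
    list(dict_spans = dict_spans, seqs = seqs, train_ids = train_ids,
         dev_ids = dev_ids)
  })
  emb <- stage("embed", {
    e <- train_char_vectors(paragraphs, dim = 100L, window = 5L,
                            seed = config$seed)
    write_embeddings(e, paths$embeddings)
    e
  })
  model <- stage("train", {
    mdl <- train_tagger(ann$seqs[ann$train_ids], ann$seqs[ann$dev_ids],
                        embeddings = emb, config = config$train,
                        verbose = verbose)
    save_tagger(mdl, paths$checkpoint)
    lg <- mdl$log
    write_utf8_lines(c("epoch\tnll\tdev_f1",
                       sprintf("%d\t%.6f\t%s", lg$epoch, lg$nll,
                               ifelse(is.na(lg$dev_f1), "NA",
                                      sprintf("%.6f", lg$dev_f1)))),
                     paths$train_log)
    mdl
  })
  pred <- stage("predict", {
    pr <- predict_spans(model, paragraphs[split$test])
    write_spans(pr, paths$pred)
    pr
  })
  results <- stage("evaluate", {
    gold_test <- corpus$gold[corpus$gold$report_id %in% split$test, ,
                             drop = FALSE]
    dict_test <- ann$dict_spans[ann$dict_spans$report_id %in% split$test, ,
                                drop = FALSE]
    seed_lex <- lexicon(lex$entries[lex$entries$provenance == "seed", ,
                                    drop = FALSE])
    seed_test <- fmm_annotate_corpus(paragraphs[split$test], seed_lex)
    m_model <- strict_metrics(pred, gold_test)
    m_dict <- strict_metrics(dict_test, gold_test)
    m_seed <- strict_metrics(seed_test, gold_test)
    m_vs_dict <- strict_metrics(pred, dict_test)
    write_metrics(m_model, paths$metrics)
    write_metrics(m_vs_dict, paths$metrics_vs_dict)
    comp <- compare_methods(list(seed_dictionary = m_seed,
                                 extended_dictionary = m_dict,
                                 bilstm_crf = m_model))
    write_comparison(comp, paths$comparison)
    nov <- novel_phrases(pred, paragraphs, lex_full)
    write_utf8_lines(c("surface\tetype\tcount",
                       sprintf("%s\t%s\t%d", nov$surface, nov$etype,
                               nov$count)), paths$novel)
    list(metrics = m_model, metrics_vs_dict = m_vs_dict, comparison = comp,
         novel = nov)
  })
  log_lines <- c(sprintf("echoNER %s\tR %s",
                         as.character(utils::packageVersion("echoNER")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed\t%d", config$seed),
                 sprintf("reports\t%d", length(corpus$reports)),
                 sprintf("train/dev/test\t%d/%d/%d", length(ann$train_ids),
                         length(ann$dev_ids), length(split$test)),
                 sprintf("gold spans\t%d", nrow(corpus$gold)),
                 sprintf("dictionary spans\t%d", nrow(ann$dict_spans)),
                 log_lines,
                 sprintf("model-vs-gold micro F1\t%.6f",
                         results$metrics$overall$f1))
  write_utf8_lines(log_lines, paths$log)
  invisible(c(results, list(model = model, paths = paths)))
}
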