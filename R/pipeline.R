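#' Prepare a document for tagging
#'
#' Runs the feature-generation pipeline on one document: segmentation
#' (skipped when tokens are supplied), truecasing, morphosyntactic
#' annotation, dictionary tagging and cluster lookup, then builds the
#' first-stage feature sequences (and BIO labels when the document carries
#' gold mentions).  Dictionary tagging, cluster lookup and morphosyntax
#' are mutually independent; their order never affects the result.
#'
#' @param doc An `"anatag_document"` (tokens optional) or a string.
#' @param resources List with elements `truecase_model`, `lexicon`,
#'   `clusters` (each possibly `NULL`), `config`, `annotator`,
#'   `dict_mode`, `pos_filter`, `max_span`.
#' @return A prepared document: `doc_id`, `sentences` (annotated sentence
#'   data.frames), `features` (first-stage feature sequences), `labels`
#'   (or `NULL`), `key` (token identity keys), `tokens`.
#' @export
prepare_document <- function(doc, resources) {
  if (is.character(doc)) doc <- document(doc)
  if (is.null(doc$tokens)) doc <- segment_document(doc)
  tok <- doc$tokens
  annotator <- resources$annotator %||% "auto"
  if (annotator == "auto")
    annotator <- if (all(c("lemma", "pos", "chunk") %in% names(tok)))
      "external" else "builtin"
  tok <- annotate_morpho(tok, annotator)
  n <- nrow(tok)
  sent_ids <- if (n) unique(tok$sentence) else integer(0)
  surf_by_sent <- split(tok$surface, factor(tok$sentence, levels = sent_ids))
  if (!is.null(resources$truecase_model)) {
    tsurf <- truecase(surf_by_sent, resources$truecase_model)
    tok$surface <- unlist(tsurf, use.names = FALSE) %||% character(0)
  }
  # dictionary features over the truecased token stream
  dict <- rep(list(character(0)), n)
  if (!is.null(resources$lexicon) &&
      isTRUE(resources$config$use_dict)) {
    m <- tag_dictionary(tok, resources$lexicon,
                        mode = resources$dict_mode %||% "all",
                        pos_filter = resources$pos_filter %||% "none",
                        max_span = resources$max_span %||% 8L)
    dict <- matches_to_features(m, n)
  }
  us <- unique(tok$surface)
  clus <- rep(list(character(0)), n)
  if (!is.null(resources$clusters) &&
      isTRUE(resources$config$use_clusters)) {
    cf <- lapply(us, prefix_features, map = resources$clusters)
    clus <- cf[match(tok$surface, us)]
  }
  # orthography + char n-grams per unique surface, memoized across calls
  cache <- resources$cache
  sizes <- resources$config$char_ngram_sizes
  lf <- vector("list", length(us))
  for (i in seq_along(us)) {
    v <- if (!is.null(cache)) cache[[us[i]]]
    if (is.null(v)) {
      v <- c(orthographic_features(us[i]),
             char_ngram_features(us[i], sizes))
      if (!is.null(cache)) cache[[us[i]]] <- v
    }
    lf[[i]] <- v
  }
  local <- lf[match(tok$surface, us)]
  idx_by_sent <- split(seq_len(n), factor(tok$sentence, levels = sent_ids))
  sentences <- lapply(idx_by_sent, function(ix) {
    s <- tok[ix, c("surface", "lemma", "pos", "chunk"), drop = FALSE]
    s$dict <- dict[ix]
    s$cluster <- clus[ix]
    s$local <- local[ix]
    rownames(s) <- NULL
    s
  })
  names(sentences) <- NULL
  config1 <- resources$config
  config1$use_nonlocal <- FALSE
  features <- lapply(sentences, build_feature_sequence, config = config1)
  labels <- NULL
  if (!is.null(doc$mentions) && !is.null(doc$text)) {
    flat <- encode_bio(tok, doc$mentions)
    labels <- lapply(idx_by_sent, function(ix) flat[ix])
    names(labels) <- NULL
  }
  list(doc_id = doc$doc_id, doc = doc, sentences = sentences,
       features = features, labels = labels,
       key = tolower(tok$surface), tokens = tok)
}

#' Fit an anatomical entity tagger
#'
#' The main fitting function: takes a standoff-annotated corpus and the
#' optional lexical resources, runs the full feature pipeline, and trains
#' a linear-chain CRF (optionally a two-stage pair whose second stage uses
#' document-level non-local features built by k-fold cross-prediction).
#' When a development set and parameter grids are supplied, the L2
#' coefficient and B-label decoding bias are selected by development-set
#' right-boundary F-score.
#'
#' @param corpus List of `"anatag_document"`s with gold mentions, or a
#'   `"synth_corpus"` (its documents and feature lexicon are used).
#' @param types Entity type inventory (`NULL` for single-class tagging).
#' @param lexicon An `"anatag_lexicon"` for dictionary features, or
#'   `NULL`.
#' @param clusters A `"cluster_map"` for Brown-cluster prefix features, or
#'   `NULL`.
#' @param truecase_model A `"case_model"`, `TRUE` to train one from the
#'   corpus itself, or `NULL` for no truecasing.
#' @param config A [feature_config()].
#' @param annotator `"auto"`, `"external"` (gold/CoNLL columns required)
#'   or `"builtin"`.
#' @param dict_mode,pos_filter,max_span Dictionary tagging settings
#'   ([tag_dictionary()]); the default tags all candidate spans with no
#'   POS filter.
#' @param l2 L2 regularization coefficient (overridden by grid search).
#' @param bias Default [decode_config()] used at prediction time
#'   (overridden by grid search).
#' @param two_stage Train the second-stage model with non-local features?
#' @param k_folds Folds for second-stage cross-prediction (default 10).
#' @param seed Seed for fold shuffling.
#' @param max_iter L-BFGS iteration cap.
#' @param min_feature_count Rare-feature cutoff passed to [crf()]
#'   (default 2: features seen once in training are dropped).
#' @param devel Optional list of development documents for grid selection.
#' @param l2_grid,bias_grid Optional grids: numeric vectors of l2 values
#'   and of B-label bias weights.
#' @param select_typed Select by multiclass (typed) devel F (default) or
#'   single-class.
#' @param verbose Print progress.
#' @return An object of class `"anatag"`.
#' @export
anatag <- function(corpus, types = anatag_types(), lexicon = NULL,
                   clusters = NULL, truecase_model = NULL,
                   config = feature_config(),
                   annotator = c("auto", "external", "builtin"),
                   dict_mode = "all", pos_filter = "none", max_span = 8L,
                   l2 = 1, bias = decode_config(), two_stage = FALSE,
                   k_folds = 10L, seed = 1L, max_iter = 200L,
                   min_feature_count = 2L,
                   devel = NULL, l2_grid = NULL, bias_grid = NULL,
                   select_typed = TRUE, verbose = FALSE) {
  annotator <- match.arg(annotator)
  if (inherits(corpus, "synth_corpus")) {
    if (is.null(lexicon)) lexicon <- corpus$feature_lexicon
    corpus <- corpus$documents
  }
  if (!length(corpus)) stop("empty training corpus")
  labels <- bio_labels(types)
  if (isTRUE(truecase_model)) {
    streams <- lapply(corpus, function(d) {
      if (is.null(d$tokens)) d <- segment_document(d)
      split(d$tokens$surface, d$tokens$sentence)
    })
    truecase_model <- train_truecaser(
      truecase_token_stream(unlist(streams, recursive = FALSE)))
  }
  resources <- list(truecase_model = truecase_model, lexicon = lexicon,
                    clusters = clusters, config = config,
                    annotator = annotator, dict_mode = dict_mode,
                    pos_filter = pos_filter, max_span = max_span,
                    cache = new.env(parent = emptyenv()))
  if (verbose) message("preparing ", length(corpus), " documents")
  prep <- lapply(corpus, prepare_document, resources = resources)
  if (!is.null(types)) {
    seen <- setdiff(unique(unlist(lapply(corpus, function(d)
      d$mentions$type))), types)
    if (length(seen))
      stop(sprintf("mention types outside the inventory: %s",
                   paste(seen, collapse = ", ")))
  }
  x <- unlist(lapply(prep, `[[`, "features"), recursive = FALSE)
  y <- unlist(lapply(prep, `[[`, "labels"), recursive = FALSE)
  fit_at <- function(l2v) {
    if (verbose) message("training stage-1 CRF (l2=", l2v, ")")
    m1 <- crf(x, y, labels, l2 = l2v, max_iter = max_iter,
              min_feature_count = min_feature_count, verbose = verbose)
    attr(m1, "fc_hash") <- feature_config_hash(config)
    m2 <- NULL
    if (two_stage) {
      if (verbose) message("building second-stage data (k=", k_folds, ")")
      ss <- make_second_stage_training(prep, labels, config, l2 = l2v,
                                       max_iter = max_iter, k = k_folds,
                                       seed = seed,
                                       min_feature_count = min_feature_count)
      m2 <- crf(unlist(ss$x2, recursive = FALSE), y, labels, l2 = l2v,
                max_iter = max_iter,
                min_feature_count = min_feature_count, verbose = verbose)
      attr(m2, "fc_hash") <- feature_config_hash(config)
    }
    list(m1 = m1, m2 = m2)
  }
  grid_log <- NULL
  if (!is.null(devel) && (!is.null(l2_grid) || !is.null(bias_grid))) {
    l2_grid <- l2_grid %||% l2
    bias_grid <- bias_grid %||% bias$B
    best <- NULL
    for (l2v in l2_grid) {
      ms <- fit_at(l2v)
      obj <- structure(list(model1 = ms$m1, model2 = ms$m2,
                            resources = resources, config = config,
                            types = types, labels = labels,
                            bias = decode_config(), l2 = l2v,
                            two_stage = two_stage),
                       class = "anatag")
      for (bv in bias_grid) {
        dc <- decode_config(B = bv)
        pred <- predict(obj, devel, bias = dc)
        f <- score_mentions(devel, pred, "right_boundary",
                            typed = select_typed)$f1
        grid_log <- rbind(grid_log,
                          data.frame(l2 = l2v, B_bias = bv, devel_f1 = f))
        if (is.null(best) || f > best$f) best <- list(ms = ms, l2 = l2v,
                                                      dc = dc, f = f)
      }
    }
    if (verbose) message(sprintf("selected l2=%g, B-bias=%g (devel F=%.4f)",
                                 best$l2, best$dc$B, best$f))
    ms <- best$ms; l2 <- best$l2; bias <- best$dc
  } else {
    ms <- fit_at(l2)
  }
  structure(list(model1 = ms$m1, model2 = ms$m2, resources = resources,
                 config = config, types = types, labels = labels,
                 bias = bias, l2 = l2, two_stage = two_stage,
                 k_folds = if (two_stage) k_folds else NA_integer_,
                 seed = seed, grid = grid_log,
                 n_train_docs = length(corpus)),
            class = "anatag")
}

#' @export
print.anatag <- function(x, ...) {
  cat(sprintf("Anatomical entity tagger (%s, %s)\n",
              if (is.null(x$types)) "single-class"
              else sprintf("%d types", length(x$types)),
              if (x$two_stage) "two-stage" else "single-stage"))
  cat(sprintf("  trained on %d documents; l2=%g; B-bias=%g\n",
              x$n_train_docs, x$l2, x$bias$B))
  cat(sprintf("  stage 1: %d features, %d labels\n",
              length(x$model1$features), length(x$labels)))
  if (!is.null(x$model2))
    cat(sprintf("  stage 2: %d features (non-local augmented)\n",
                length(x$model2$features)))
  invisible(x)
}

#' @export
summary.anatag <- function(object, ...) {
  print(object)
  res <- object$resources
  cat("resources:\n")
  cat(sprintf("  truecasing: %s\n",
              if (is.null(res$truecase_model)) "off" else
                sprintf("%d keys", length(res$truecase_model$dominant))))
  cat(sprintf("  dictionary: %s (mode=%s, pos_filter=%s)\n",
              if (is.null(res$lexicon)) "off" else
                sprintf("%d entries", length(res$lexicon$keys)),
              res$dict_mode, res$pos_filter))
  cat(sprintf("  clusters: %s\n",
              if (is.null(res$clusters)) "off" else
                sprintf("%d words", length(res$clusters$assignments))))
  if (!is.null(object$grid)) {
    cat("grid search (devel right-boundary F):\n")
    print(object$grid, row.names = FALSE)
  }
  invisible(object)
}

#' Tag documents with a fitted tagger
#'
#' Runs the full pipeline on new documents and returns them with
#' predicted mentions (any existing mentions are replaced).  Inputs may
#' be `"anatag_document"`s (pre-tokenized or not) or raw strings.
#'
#' @param object An `"anatag"` model.
#' @param newdata List of documents / strings, or a single one.
#' @param bias [decode_config()]; defaults to the model's stored bias.
#' @param ... Unused.
#' @return List of documents with predicted `mentions`.
#' @export
predict.anatag <- function(object, newdata, bias = object$bias, ...) {
  if (inherits(newdata, "anatag_document") || is.character(newdata))
    newdata <- list(newdata)
  if (inherits(newdata, "synth_corpus")) newdata <- newdata$documents
  lapply(newdata, function(doc) {
    prep <- prepare_document(doc, object$resources)
    lab <- if (!is.null(object$model2))
      two_stage_predict(object$model1, object$model2, prep, bias = bias,
                        config = object$config)
    else predict(object$model1, prep$features, bias = bias)
    out <- prep$doc
    ment <- decode_labels_to_mentions(lab, prep, out$text)
    out$mentions <- ment
    out
  })
}

decode_labels_to_mentions <- function(lab, prep, text) {
  off <- 0L
  parts <- list()
  for (s in seq_along(prep$sentences)) {
    n <- nrow(prep$sentences[[s]])
    tok <- prep$tokens[off + seq_len(n), , drop = FALSE]
    parts[[s]] <- decode_bio(lab[[s]], tok)
    off <- off + n
  }
  m <- do.call(rbind, parts)
  if (is.null(m) || !nrow(m)) return(mentions())
  mentions(m$start, m$end, m$type, doc_text = text)
}

#' Evaluate a fitted tagger on gold documents
#'
#' @param object An `"anatag"` model.
#' @param docs Gold-annotated documents.
#' @param criterion,typed Passed to [score_mentions()].
#' @param bias Decoding bias.
#' @return An `"anatag_eval"`.
#' @export
anatag_evaluate <- function(object, docs,
                            criterion = c("right_boundary", "exact"),
                            typed = TRUE, bias = object$bias) {
  if (inherits(docs, "synth_corpus")) docs <- docs$documents
  pred <- predict(object, docs, bias = bias)
  score_mentions(docs, pred, match.arg(criterion), typed = typed)
}

#' Tag documents and return standoff annotation strings
#'
#' @param object An `"anatag"` model.
#' @param newdata Documents or raw texts.
#' @param bias Decoding bias.
#' @return Named character vector of .ann contents (one per document),
#'   with a per-type mention count summary as the `"counts"` attribute.
#' @export
tag_standoff <- function(object, newdata, bias = object$bias) {
  docs <- predict(object, newdata, bias = bias)
  out <- vapply(docs, write_standoff, character(1))
  names(out) <- vapply(docs, `[[`, character(1), "doc_id")
  types <- unlist(lapply(docs, function(d) d$mentions$type))
  attr(out, "counts") <- table(factor(types,
                                      levels = object$types %||% "Entity"))
  out
}
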