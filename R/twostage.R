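pick_tag <- function(tags, positions) {
  tt <- unique(tags)
  cnt <- vapply(tt, function(t) sum(tags == t), integer(1))
  fp <- vapply(tt, function(t) min(positions[tags == t]), numeric(1))
  tt[order(-cnt, fp)][1]   # ties: tag occurring earliest in the document
}

#' Document-level non-local tag statistics
#'
#' For every token, statistics over all positions in the same document
#' with an identical token (case-insensitive comparison of truecased
#' surfaces), including the token itself: the most frequent first-stage
#' tag (`mft`), the most frequent non-"O" tag (`mfnt`, absent when every
#' occurrence is "O"), and the tag of the first occurrence (`first`).
#' These let a second-stage model carry type evidence from unambiguous
#' mentions to ambiguous ones elsewhere in the document.
#'
#' @param keys Character vector of token identity keys for one document
#'   (one per token, in document order).
#' @param labels First-stage tags, parallel to `keys`.
#' @return `data.frame(mft, mfnt, first)`; `mfnt` is `NA` where absent.
#' @export
compute_nonlocal <- function(keys, labels) {
  if (length(keys) != length(labels))
    stop("keys and labels lengths differ")
  n <- length(keys)
  mft <- mfnt <- first <- rep(NA_character_, n)
  for (g in split(seq_len(n), keys)) {
    tags <- labels[g]
    mft[g] <- pick_tag(tags, g)
    nonO <- tags != "O"
    if (any(nonO)) mfnt[g] <- pick_tag(tags[nonO], g[nonO])
    first[g] <- tags[1L]
  }
  data.frame(mft = mft, mfnt = mfnt, first = first,
             stringsAsFactors = FALSE)
}

nonlocal_features <- function(nl) {
  lapply(seq_len(nrow(nl)), function(i) {
    f <- c(paste0("NL-MFT=", nl$mft[i]), paste0("NL-FIRST=", nl$first[i]))
    if (!is.na(nl$mfnt[i])) f <- c(f, paste0("NL-MFNT=", nl$mfnt[i]))
    f
  })
}

# attach non-local features derived from (predicted) labels to a prepared
# document and rebuild its feature sequences with the non-local family on
augment_nonlocal <- function(prep, flat_labels, config) {
  nl <- compute_nonlocal(prep$key, flat_labels)
  nlf <- nonlocal_features(nl)
  config$use_nonlocal <- TRUE
  off <- 0L
  feats <- vector("list", length(prep$sentences))
  for (s in seq_along(prep$sentences)) {
    sent <- prep$sentences[[s]]
    n <- nrow(sent)
    sent$nonlocal <- nlf[off + seq_len(n)]
    feats[[s]] <- build_feature_sequence(sent, config)
    off <- off + n
  }
  feats
}

#' Build second-stage training data by cross-prediction
#'
#' Partitions the training documents into `k` folds (document-level,
#' seeded shuffle); for each fold, a first-stage model trained on the
#' other `k - 1` folds predicts its tags, and non-local features computed
#' from those predictions augment the fold's feature sequences.  First
#' stage models never see the documents they annotate, and gold labels are
#' never used to build the non-local features.
#'
#' @param prep_docs List of prepared documents (see [anatag()]).
#' @param labels Label set.
#' @param config Base [feature_config()].
#' @param l2,max_iter,min_feature_count CRF training settings for the
#'   fold models.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @return List with `x2` (augmented feature sequences per document),
#'   `folds` (fold id per document).
#' @export
make_second_stage_training <- function(prep_docs, labels, config,
                                       l2 = 1, max_iter = 200L, k = 10L,
                                       seed = 1L, min_feature_count = 1L) {
  n <- length(prep_docs)
  if (k < 2L || k > n)
    stop(sprintf("k must be in 2..%d (number of documents)", n))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  x2 <- vector("list", n)
  for (f in seq_len(k)) {
    train_idx <- which(folds != f); pred_idx <- which(folds == f)
    m <- crf(unlist(lapply(prep_docs[train_idx], `[[`, "features"),
                    recursive = FALSE),
             unlist(lapply(prep_docs[train_idx], `[[`, "labels"),
                    recursive = FALSE),
             labels, l2 = l2, max_iter = max_iter,
             min_feature_count = min_feature_count)
    for (d in pred_idx) {
      pred <- predict(m, prep_docs[[d]]$features)
      x2[[d]] <- augment_nonlocal(prep_docs[[d]],
                                  unlist(pred, use.names = FALSE), config)
    }
  }
  list(x2 = x2, folds = folds)
}

#' Two-stage decoding of one prepared document
#'
#' Applies the first-stage model, derives document-level non-local
#' features from its tagging, and lets the second-stage model produce the
#' final labels.
#'
#' @param model1,model2 First- and second-stage `"anatag_crf"` models;
#'   their base feature configurations must match.
#' @param prep A prepared document.
#' @param bias [decode_config()] applied to the second-stage decode.
#' @param config Base [feature_config()].
#' @return List of final label sequences (one per sentence).
#' @export
two_stage_predict <- function(model1, model2, prep, bias = decode_config(),
                              config = feature_config()) {
  h1 <- attr(model1, "fc_hash"); h2 <- attr(model2, "fc_hash")
  if (!is.null(h1) && !is.null(h2) && !identical(h1, h2))
    stop("feature configuration mismatch between stage models")
  lab1 <- predict(model1, prep$features)
  x2 <- augment_nonlocal(prep, unlist(lab1, use.names = FALSE), config)
  predict(model2, x2, bias = bias)
}
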