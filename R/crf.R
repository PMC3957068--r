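#' BIO label set for a type inventory
#'
#' Each token is labeled (B)eginning, (I)nside or (O)utside a mention, with
#' B/I carrying the entity type (`B-Cell`).  For the 12-type anatomical
#' inventory this gives 25 labels; single-class tagging (one generic type)
#' gives 3.
#'
#' @param types Character vector of entity types; `NULL` for single-class
#'   mode (one type `"Entity"`).
#' @return Character vector of labels, `"O"` first.
#' @export
bio_labels <- function(types = anatag_types()) {
  if (is.null(types)) types <- "Entity"
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

bio_class <- function(labels) {
  cls <- substr(labels, 1L, 1L)
  cls[labels == "O"] <- "O"
  cls
}

#' Encode mentions as a BIO label sequence
#'
#' The first token of each mention gets `B-<type>`, subsequent tokens
#' `I-<type>`, everything else `O`.  A mention boundary falling inside a
#' token is, by default, snapped outward to token boundaries with a
#' warning; `boundary = "error"` rejects it.
#'
#' @param tokens Token `data.frame` with `start`, `end` offsets.
#' @param mention_tab Mention table ([mentions()]).
#' @param boundary `"snap"` or `"error"`.
#' @return Character vector of labels, one per token.
#' @export
encode_bio <- function(tokens, mention_tab, boundary = c("snap", "error")) {
  boundary <- match.arg(boundary)
  labels <- rep("O", nrow(tokens))
  if (!nrow(mention_tab)) return(labels)
  for (i in seq_len(nrow(mention_tab))) {
    ms <- mention_tab$start[i]; me <- mention_tab$end[i]
    covered <- which(tokens$end > ms & tokens$start < me)
    if (!length(covered))
      stop(sprintf("mention [%d,%d) covers no token", ms, me))
    if (tokens$start[covered[1]] != ms ||
        tokens$end[covered[length(covered)]] != me) {
      msg <- sprintf("mention [%d,%d) not aligned to token boundaries", ms, me)
      if (boundary == "error") stop(msg)
      warning(paste(msg, "- snapped outward"), call. = FALSE)
    }
    labels[covered[1]] <- paste0("B-", mention_tab$type[i])
    if (length(covered) > 1L)
      labels[covered[-1L]] <- paste0("I-", mention_tab$type[i])
  }
  labels
}

#' Decode a BIO label sequence into mentions
#'
#' Total function over arbitrary label sequences: a mention is a maximal
#' run `B-t (I-t)*`; an `I-t` with no compatible predecessor (after `O` or
#' a different type) is repaired to `B-t`.
#'
#' @param labels Character vector of BIO labels.
#' @param tokens Token `data.frame` with `start`, `end` character offsets
#'   (used to produce mention character spans).
#' @return A mention table with `start`, `end`, `type` (no `text`).
#' @export
decode_bio <- function(labels, tokens) {
  n <- length(labels)
  starts <- integer(); ends <- integer(); types <- character()
  cur_type <- NULL; cur_start <- NA_integer_; cur_end <- NA_integer_
  flush <- function() {
    if (!is.null(cur_type)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, cur_end)
      types <<- c(types, cur_type)
    }
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") { flush(); cur_type <- NULL; next }
    cls <- substr(lab, 1L, 1L); typ <- substr(lab, 3L, nchar(lab))
    if (cls == "B" || is.null(cur_type) || typ != cur_type) {
      flush()
      cur_type <- typ; cur_start <- tokens$start[i]
    }
    cur_end <- tokens$end[i]
  }
  flush()
  m <- data.frame(start = starts, end = ends, type = types,
                  text = rep(NA_character_, length(starts)),
                  stringsAsFactors = FALSE)
  rownames(m) <- NULL
  m
}

# flatten a list of feature sequences into CSR structure against a feature
# vocabulary (built when vocab = NULL, in order of first appearance;
# min_count drops features with fewer corpus occurrences)
crf_pack <- function(x, vocab = NULL, min_count = 1L) {
  n_tok_per_seq <- vapply(x, length, integer(1))
  flat <- unlist(x, recursive = FALSE, use.names = FALSE)
  counts <- if (length(flat)) lengths(flat) else integer(0)
  allf <- unlist(flat, use.names = FALSE)
  if (is.null(allf)) allf <- character(0)
  if (is.null(vocab)) {
    vocab <- unique(allf)
    if (min_count > 1L && length(vocab)) {
      tab <- tabulate(match(allf, vocab), nbins = length(vocab))
      vocab <- vocab[tab >= min_count]
    }
  }
  ids <- match(allf, vocab) - 1L
  keep <- !is.na(ids)
  if (!all(keep)) {
    # unseen features: drop (they contribute zero score)
    grp <- rep.int(seq_along(counts), counts)
    counts <- if (length(counts)) tabulate(grp[keep], nbins = length(counts))
              else counts
    ids <- ids[keep]
  }
  list(feat = as.integer(ids),
       tok_ptr = c(0L, cumsum(as.integer(counts))),
       seq_ptr = c(0L, cumsum(n_tok_per_seq)),
       vocab = vocab)
}

#' Fit a linear-chain CRF
#'
#' L2-regularized maximum conditional likelihood over string-valued token
#' features, optimized with L-BFGS on the exact forward-backward gradient.
#' Deterministic given the data, label set and configuration.
#'
#' @param x List of feature sequences: one list per sentence, containing
#'   one character vector of features per token.
#' @param y List of label sequences (character), parallel to `x`.
#' @param labels Label set ([bio_labels()]); every label in `y` must be in
#'   it.
#' @param l2 L2 regularization coefficient (> 0); the penalty is
#'   `l2/2 * ||theta||^2`.
#' @param max_iter Maximum L-BFGS iterations.
#' @param min_feature_count Features occurring fewer times in the training
#'   data are dropped (default 1: keep everything); the conventional
#'   rare-feature cutoff of CRF taggers.
#' @param verbose Print optimizer progress.
#' @return An object of class `"anatag_crf"` with elements `weights`
#'   (flat parameter vector), `features` (feature vocabulary), `labels`,
#'   `l2`, `niter`, `nll` (final penalized objective) and `convergence`.
#' @export
crf <- function(x, y, labels, l2 = 1, max_iter = 200L,
                min_feature_count = 1L, verbose = FALSE) {
  if (!length(x)) stop("empty training set")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (l2 <= 0) stop("l2 coefficient must be positive")
  ylab <- unlist(y, use.names = FALSE)
  bad <- setdiff(unique(ylab), labels)
  if (length(bad))
    stop(sprintf("labels outside the label set: %s",
                 paste(bad, collapse = ", ")))
  if (any(vapply(x, length, integer(1)) != vapply(y, length, integer(1))))
    stop("feature and label sequence lengths differ")
  packed <- crf_pack(x, min_count = min_feature_count)
  yv <- match(ylab, labels) - 1L
  F_ <- length(packed$vocab); L_ <- length(labels)
  npar <- F_ * L_ + L_ * L_
  cache <- new.env(parent = emptyenv())
  obj <- function(par) {
    r <- crf_nll_grad(par, packed$feat, packed$tok_ptr, packed$seq_ptr,
                      yv, F_, L_, l2)
    cache$par <- par; cache$grad <- r$grad
    r$nll
  }
  grd <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$grad)
    crf_nll_grad(par, packed$feat, packed$tok_ptr, packed$seq_ptr,
                 yv, F_, L_, l2)$grad
  }
  fit <- optim(numeric(npar), obj, grd, method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter),
                              trace = if (verbose) 1L else 0L,
                              factr = 1e9))
  structure(list(weights = fit$par, features = packed$vocab,
                 labels = labels, l2 = l2,
                 niter = fit$counts[["function"]], nll = fit$value,
                 convergence = fit$convergence),
            class = "anatag_crf")
}

#' @export
print.anatag_crf <- function(x, ...) {
  cat(sprintf(
    "<anatag_crf: %d labels, %d features, l2=%g, final objective %.3f>\n",
    length(x$labels), length(x$features), x$l2, x$nll))
  invisible(x)
}

#' @export
coef.anatag_crf <- function(object, ...) {
  F_ <- length(object$features); L_ <- length(object$labels)
  state <- matrix(object$weights[seq_len(F_ * L_)], nrow = L_,
                  dimnames = list(object$labels, object$features))
  trans <- t(matrix(object$weights[F_ * L_ + seq_len(L_ * L_)], nrow = L_))
  dimnames(trans) <- list(from = object$labels, to = object$labels)
  list(state = state, trans = trans)
}

#' Decoding configuration: additive label bias
#'
#' Bias weights are added to every position's label scores before Viterbi
#' decoding, trading precision for recall without retraining: lowering the
#' `O` weight or raising `B`/`I` weights makes the decoder produce more
#' entity mentions.  Granularity is the label class {O, B, I}, with
#' optional per-label overrides.
#'
#' @param O,B,I Additive weight per label class (defaults 0: standard
#'   Viterbi).
#' @param per_label Optional named numeric vector of per-label overrides
#'   (e.g. `c("B-Cell" = 0.5)`).
#' @return An object of class `"decode_config"`.
#' @export
decode_config <- function(O = 0, B = 0, I = 0, per_label = NULL) {
  stopifnot(is.finite(O), is.finite(B), is.finite(I),
            is.null(per_label) || all(is.finite(per_label)))
  structure(list(O = O, B = B, I = I, per_label = per_label),
            class = "decode_config")
}

expand_bias <- function(config, labels) {
  cls <- bio_class(labels)
  bias <- c(O = config$O, B = config$B, I = config$I)[cls]
  bias <- unname(bias)
  if (!is.null(config$per_label)) {
    idx <- match(names(config$per_label), labels)
    if (anyNA(idx)) stop("per_label bias names outside the label set")
    bias[idx] <- unname(config$per_label)
  }
  bias
}

#' Predict label sequences with a fitted CRF
#'
#' Viterbi-optimal label sequences, optionally under additive label bias
#' ([decode_config()]); zero bias reproduces the standard unbiased decode.
#' Features unseen in training contribute zero score.
#'
#' @param object An `"anatag_crf"`.
#' @param newdata List of feature sequences.
#' @param bias A `"decode_config"` (default: no bias).
#' @param ... Unused.
#' @return List of character label sequences.
#' @export
predict.anatag_crf <- function(object, newdata, bias = decode_config(),
                               ...) {
  if (!length(newdata)) return(list())
  packed <- crf_pack(newdata, vocab = object$features)
  bv <- expand_bias(bias, object$labels)
  ids <- crf_viterbi(object$weights, packed$feat, packed$tok_ptr,
                     packed$seq_ptr, length(object$features),
                     length(object$labels), bv)
  lens <- vapply(newdata, length, integer(1))
  labs <- object$labels[ids + 1L]
  out <- vector("list", length(lens))
  pos <- 0L
  for (i in seq_along(lens)) {
    out[[i]] <- labs[pos + seq_len(lens[i])]
    pos <- pos + lens[i]
  }
  out
}

#' Negative conditional log-likelihood of labeled data under a CRF
#'
#' @param model An `"anatag_crf"`.
#' @param x,y Feature and label sequences as in [crf()].
#' @param penalized Include the `l2/2 ||theta||^2` penalty?
#' @return A single number.
#' @export
crf_neg_loglik <- function(model, x, y, penalized = FALSE) {
  packed <- crf_pack(x, vocab = model$features)
  yv <- match(unlist(y, use.names = FALSE), model$labels) - 1L
  if (anyNA(yv)) stop("labels outside the model's label set")
  crf_nll_grad(model$weights, packed$feat, packed$tok_ptr, packed$seq_ptr,
               yv, length(model$features), length(model$labels),
               if (penalized) model$l2 else 0)$nll
}
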