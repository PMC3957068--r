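check_nonoverlap <- function(m, what) {
  if (nrow(m) < 2L) return(invisible())
  m <- m[order(m$start, m$end), , drop = FALSE]
  if (any(m$start[-1L] < m$end[-nrow(m)]))
    stop(sprintf("overlapping mentions in %s set", what))
  invisible()
}

#' Match predicted against gold mentions in one document
#'
#' Greedy one-to-one matching.  Under the `"right_boundary"` criterion
#' (the primary one) a prediction matches a gold mention when their end
#' offsets agree — a left-boundary disagreement is forgiven; `"exact"`
#' requires both offsets.  With `typed = TRUE` the types must also be
#' equal.  Each mention matches at most once; among golds sharing the
#' required boundary (impossible for non-overlapping sets, checked), the
#' pair with the closer left boundary would win.
#'
#' @param gold,pred Mention tables ([mentions()]), each internally
#'   non-overlapping.
#' @param criterion `"right_boundary"` or `"exact"`.
#' @param typed Require type equality?
#' @return List with `tp`, `fp`, `fn` counts and a `pairs` data.frame of
#'   matched (gold_row, pred_row) indices.
#' @export
match_mentions <- function(gold, pred,
                           criterion = c("right_boundary", "exact"),
                           typed = TRUE) {
  criterion <- match.arg(criterion)
  check_nonoverlap(gold, "gold"); check_nonoverlap(pred, "predicted")
  key <- function(m) {
    k <- as.character(m$end)
    if (criterion == "exact") k <- paste(m$start, k)
    if (typed) k <- paste(k, m$type)
    k
  }
  gk <- key(gold); pk <- key(pred)
  # non-overlap makes keys unique within a set, so match() is one-to-one
  idx <- match(pk, gk)
  matched <- !is.na(idx) & !duplicated(idx)
  pairs <- data.frame(gold_row = idx[matched],
                      pred_row = which(matched))
  tp <- sum(matched)
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp, pairs = pairs)
}

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Mention-level corpus evaluation
#'
#' Micro-averaged precision, recall and F1 over documents, on the entity
#' mention level.  `typed = FALSE` gives the single-class setting (every
#' mention relabeled to one type before matching); in the multiclass
#' setting types must match exactly and a per-type breakdown is reported.
#'
#' @param gold_docs,pred_docs Lists of `"anatag_document"`s with matching
#'   `doc_id`s.
#' @inheritParams match_mentions
#' @return An object of class `"anatag_eval"`: overall `tp`/`fp`/`fn`,
#'   `precision`, `recall`, `f1`, the evaluation `criterion` and `typed`
#'   flag, and (typed mode) a `per_type` data.frame.
#' @export
score_mentions <- function(gold_docs, pred_docs,
                           criterion = c("right_boundary", "exact"),
                           typed = TRUE) {
  criterion <- match.arg(criterion)
  gid <- vapply(gold_docs, `[[`, character(1), "doc_id")
  pid <- vapply(pred_docs, `[[`, character(1), "doc_id")
  if (!setequal(gid, pid) || anyDuplicated(gid))
    stop(sprintf("document id mismatch; missing from predictions: %s",
                 paste(setdiff(gid, pid), collapse = ", ")))
  pred_docs <- pred_docs[match(gid, pid)]
  tp <- fp <- fn <- 0L
  type_counts <- list()
  bump <- function(tab, types, field) {
    for (t in types) {
      if (is.null(tab[[t]])) tab[[t]] <- c(tp = 0L, fp = 0L, fn = 0L)
      tab[[t]][field] <- tab[[t]][field] + 1L
    }
    tab
  }
  for (i in seq_along(gold_docs)) {
    g <- gold_docs[[i]]$mentions; p <- pred_docs[[i]]$mentions
    if (!typed) {
      g$type <- rep("Entity", nrow(g)); p$type <- rep("Entity", nrow(p))
      g <- mentions(g$start, g$end, g$type)
      p <- mentions(p$start, p$end, p$type)
    }
    m <- match_mentions(g, p, criterion, typed = TRUE)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (typed) {
      type_counts <- bump(type_counts, g$type[m$pairs$gold_row], "tp")
      type_counts <- bump(type_counts,
                          p$type[setdiff(seq_len(nrow(p)), m$pairs$pred_row)],
                          "fp")
      type_counts <- bump(type_counts,
                          g$type[setdiff(seq_len(nrow(g)), m$pairs$gold_row)],
                          "fn")
    }
  }
  res <- as.list(prf(tp, fp, fn))
  res <- c(res, list(tp = tp, fp = fp, fn = fn, criterion = criterion,
                     typed = typed))
  if (typed && length(type_counts)) {
    pt <- do.call(rbind, lapply(sort(names(type_counts)), function(t) {
      cc <- type_counts[[t]]
      data.frame(type = t, tp = unname(cc["tp"]), fp = unname(cc["fp"]),
                 fn = unname(cc["fn"]),
                 t(prf(cc["tp"], cc["fp"], cc["fn"])), row.names = NULL)
    }))
    res$per_type <- pt
  }
  structure(res, class = "anatag_eval")
}

#' @export
print.anatag_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Mention-level evaluation (%s match, %s)\n",
              sub("_", " ", x$criterion),
              if (x$typed) "multiclass" else "single-class"))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.*f  recall %.*f  F1 %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f1))
  if (!is.null(x$per_type)) {
    cat("  per type:\n")
    pt <- x$per_type
    for (i in seq_len(nrow(pt)))
      cat(sprintf("    %-32s P %.*f R %.*f F %.*f (n=%d)\n", pt$type[i],
                  digits, pt$precision[i], digits, pt$recall[i],
                  digits, pt$f1[i], pt$tp[i] + pt$fn[i]))
  }
  invisible(x)
}
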