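#' Read a Brown-cluster map
#'
#' Reads the de-facto interchange TSV of hierarchical clustering output:
#' `bitstring TAB word [TAB count]` per line.  Identifiers must be
#' non-empty strings over {0,1}; a word may appear only once.
#'
#' @param content TSV content.
#' @return An object of class `"cluster_map"`: named character vector
#'   `assignments` (word -> bit string) and `n_clusters`.
#' @export
read_clusters <- function(content) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(cluster_map(character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(!lengths(f) %in% c(2L, 3L)))
    stop("cluster lines must have 2 or 3 TSV fields")
  bits <- vapply(f, `[[`, character(1), 1L)
  words <- vapply(f, `[[`, character(1), 2L)
  bad <- which(!grepl("^[01]+$", bits))
  if (length(bad))
    stop(sprintf("non-binary cluster identifier on line %d: %s",
                 bad[1], dQuote(bits[bad[1]])))
  dup <- which(duplicated(words))
  if (length(dup))
    stop(sprintf("duplicate word in cluster map: %s", dQuote(words[dup[1]])))
  cluster_map(setNames(bits, words))
}

cluster_map <- function(assignments) {
  structure(list(assignments = assignments,
                 n_clusters = length(unique(unname(assignments)))),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map: %d words, %d clusters>\n",
              length(x$assignments), x$n_clusters))
  invisible(x)
}

#' Serialize a cluster map to TSV
#' @param map A `"cluster_map"`.
#' @return TSV content.
#' @export
write_clusters <- function(map) {
  if (!length(map$assignments)) return("")
  paste0(paste(unname(map$assignments), names(map$assignments),
               sep = "\t", collapse = "\n"), "\n")
}

#' Hierarchical cluster prefix features
#'
#' For a word with cluster identifier `b`, emits features `BC<k>=<prefix>`
#' for each requested prefix length `k` (defaults 4, 6, 10); prefixes of a
#' hierarchical bit string denote increasingly coarse clusters.  When the
#' identifier is shorter than `k` the whole identifier is used, so features
#' of different granularity may coincide.  Unknown words get no features.
#'
#' @param word Word to look up (lookup is on the lowercased form; induction
#'   corpora are conventionally lowercased).
#' @param map A `"cluster_map"`.
#' @param prefix_lengths Integer vector of prefix lengths.
#' @return Character vector of at most `length(prefix_lengths)` features.
#' @export
prefix_features <- function(word, map, prefix_lengths = c(4L, 6L, 10L)) {
  b <- unname(map$assignments[tolower(word)])
  if (is.na(b)) return(character(0))
  paste0("BC", prefix_lengths, "=",
         substr(rep(b, length(prefix_lengths)), 1L,
                pmin(prefix_lengths, nchar(b))))
}

#' Induce Brown clusters on a small corpus
#'
#' Greedy agglomerative hard clustering of the vocabulary maximizing the
#' average mutual information of class bigrams: starting from one class per
#' word, repeatedly merge the pair of classes whose merge yields the
#' highest post-merge AMI, until `c` classes remain.  The remaining merges
#' down to a single class define a binary tree whose root-to-leaf paths
#' give each class its bit-string identifier (the larger-count child of
#' each merge takes bit 0).  Fully deterministic given the corpus and
#' parameters: classes are seeded in decreasing word-frequency order and
#' ties broken by index.  Intended for desk-scale corpora (small
#' vocabularies); large-scale induction should be done with a dedicated
#' tool and imported via [read_clusters()].
#'
#' @param corpus List of character vectors (tokenized sentences).
#' @param c Number of clusters (2 <= c <= vocabulary size).
#' @param seed Unused source of randomness kept for interface stability;
#'   the algorithm is deterministic.
#' @return A `"cluster_map"`.
#' @export
induce_brown_clusters <- function(corpus, c, seed = 1L) {
  words <- unlist(corpus, use.names = FALSE)
  if (!length(words)) stop("empty corpus")
  freq <- table(words)
  freq <- freq[order(-as.integer(freq), names(freq))]
  vocab <- names(freq)
  V <- length(vocab)
  if (c < 2L) stop("c must be >= 2")
  if (c > V) stop(sprintf("c (%d) exceeds vocabulary size (%d)", c, V))
  big <- matrix(0, V, V)   # class-bigram counts; classes start as words
  for (s in corpus) {
    ids <- match(s, vocab)
    if (length(ids) > 1L) {
      a <- ids[-length(ids)]; b <- ids[-1L]
      for (k in seq_along(a)) big[a[k], b[k]] <- big[a[k], b[k]] + 1
    }
  }
  cnt <- as.integer(freq)  # word-occurrence totals per class
  active <- rep(TRUE, V)
  merge_log <- list()      # chronological: j folded into i
  n_active <- V
  while (n_active > 1L) {
    act <- which(active)
    best <- NULL; best_ami <- -Inf
    for (jj in seq_along(act)) for (ii in seq_len(jj - 1L)) {
      i <- act[ii]; j <- act[jj]
      ami <- ami_after_merge(big, act, i, j)
      if (ami > best_ami + 1e-12) { best_ami <- ami; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge_log[[length(merge_log) + 1L]] <-
      list(i = i, j = j, n_active = n_active,
           count_i = cnt[i], count_j = cnt[j])
    big[i, ] <- big[i, ] + big[j, ]
    big[, i] <- big[, i] + big[, j]
    big[j, ] <- 0; big[, j] <- 0
    cnt[i] <- cnt[i] + cnt[j]
    active[j] <- FALSE
    n_active <- n_active - 1L
  }
  # flat clustering = state once n_active reached c; later merges are the
  # tree whose root-to-leaf paths give the bit strings
  flat <- as.list(seq_len(V))
  tree_merges <- list()
  for (m in merge_log) {
    if (m$n_active > c) {
      flat[[m$i]] <- c(flat[[m$i]], flat[[m$j]]); flat[[m$j]] <- integer(0)
    } else {
      tree_merges[[length(tree_merges) + 1L]] <- m
    }
  }
  cluster_ids <- which(lengths(flat) > 0L)
  bits <- brown_assign_bits(tree_merges, cluster_ids)
  assignments <- character(V)
  for (k in cluster_ids)
    assignments[unlist(flat[[k]])] <- bits[[as.character(k)]]
  names(assignments) <- vocab
  cluster_map(assignments)
}

# assign bit strings to the c flat clusters from the merge tree:
# tree_merges are in chronological order (c classes -> 1); replayed in
# reverse, each merge splits a node into the subtree that was rooted at i
# (bit by larger count) and the one rooted at j
brown_assign_bits <- function(tree_merges, cluster_ids) {
  ids <- as.character(cluster_ids)
  if (!length(tree_merges))
    return(setNames(as.list(rep("", length(ids))), ids))
  # forward replay tracking composition, then reverse assignment
  node <- setNames(ids, ids)  # current root label of each cluster
  comp <- setNames(lapply(ids, identity), ids)  # root -> member cluster ids
  seq_ops <- list()
  for (m in tree_merges) {
    gi <- as.character(m$i); gj <- as.character(m$j)
    seq_ops[[length(seq_ops) + 1L]] <-
      list(root = gi, left = comp[[gi]], right = comp[[gj]],
           left_first = m$count_i >= m$count_j)
    comp[[gi]] <- c(comp[[gi]], comp[[gj]])
    comp[[gj]] <- NULL
  }
  bits <- setNames(rep("", length(ids)), ids)
  for (op in rev(seq_ops)) {
    b_left <- if (op$left_first) "0" else "1"
    b_right <- if (op$left_first) "1" else "0"
    bits[op$left] <- paste0(bits[op$left], b_left)
    bits[op$right] <- paste0(bits[op$right], b_right)
  }
  as.list(bits)
}

# average mutual information of the class-bigram distribution if classes
# i and j (rows/cols of the active count matrix) were merged
ami_after_merge <- function(big, act, i, j) {
  sub <- big[act, act, drop = FALSE]
  ii <- match(i, act); jj <- match(j, act)
  sub[ii, ] <- sub[ii, ] + sub[jj, ]
  sub[, ii] <- sub[, ii] + sub[, jj]
  sub <- sub[-jj, -jj, drop = FALSE]
  class_bigram_ami(sub)
}

#' Average mutual information of a class-bigram count matrix
#'
#' The objective greedy Brown clustering maximizes:
#' `sum p(c1,c2) log( p(c1,c2) / (pl(c1) pr(c2)) )` over class pairs, with
#' left/right marginals from the bigram counts.
#'
#' @param counts Square matrix of class-bigram counts.
#' @return AMI in nats.
#' @export
class_bigram_ami <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(0)
  p <- counts / total
  pl <- rowSums(p); pr <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (pl[row(p)[nz]] * pr[col(p)[nz]])))
}
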