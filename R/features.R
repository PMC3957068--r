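#' Feature configuration
#'
#' Controls the per-token representation fed to the CRF: the context
#' window, which feature families are combined as bigrams, character
#' n-gram sizes, and which resource-derived families are active.
#'
#' @param window Tokens of context on each side of the focus token
#'   (default 2: two preceding and two following).
#' @param bigram_families Families combined at adjacent offset pairs
#'   within the window (subset of `c("W","N","L","P","C")`; `W` truecased
#'   surface, `N` normalized form, `L` lemma, `P` POS, `C` chunk).
#' @param char_ngram_sizes Character n-gram sizes at the focus token.
#' @param use_dict,use_clusters,use_nonlocal Toggle dictionary, cluster and
#'   document-level non-local feature families.
#' @return An object of class `"feature_config"`.
#' @export
feature_config <- function(window = 2L,
                           bigram_families = c("N", "P"),
                           char_ngram_sizes = c(2L, 3L, 4L),
                           use_dict = TRUE, use_clusters = TRUE,
                           use_nonlocal = FALSE) {
  if (window < 0L) stop("window must be >= 0")
  structure(list(window = as.integer(window),
                 bigram_families = bigram_families,
                 char_ngram_sizes = as.integer(char_ngram_sizes),
                 use_dict = isTRUE(use_dict),
                 use_clusters = isTRUE(use_clusters),
                 use_nonlocal = isTRUE(use_nonlocal)),
            class = "feature_config")
}

feature_config_hash <- function(config) {
  paste(config$window, paste(sort(config$bigram_families), collapse = "+"),
        paste(sort(config$char_ngram_sizes), collapse = "+"),
        config$use_dict, config$use_clusters, config$use_nonlocal,
        sep = "|")
}

#' Normalize a surface form
#'
#' Lowercases and collapses digit runs to "0": the `N` feature family.
#'
#' @param surface Character vector.
#' @return Normalized forms.
#' @export
normalize_surface <- function(surface) {
  gsub("[0-9]+", "0", tolower(surface))
}

#' Morphosyntactic annotation
#'
#' Attaches lemma, POS and chunk columns to a token table.  Two modes:
#' `"external"` passes through columns supplied with the input (the
#' replication-quality path, e.g. gold columns from CoNLL input), and
#' `"builtin"` is a deterministic heuristic fallback: closed-class lookup
#' plus suffix rules for POS, suffix-stripping lemmas, and a simple
#' noun-phrase chunker.
#'
#' @param tokens Token `data.frame` with `surface` (and `lemma`, `pos`,
#'   `chunk` in external mode).
#' @param annotator `"external"` or `"builtin"`.
#' @return The token table with `lemma`, `pos`, `chunk` columns.
#' @export
annotate_morpho <- function(tokens, annotator = c("builtin", "external")) {
  annotator <- match.arg(annotator)
  if (annotator == "external") {
    missing <- setdiff(c("lemma", "pos", "chunk"), names(tokens))
    if (length(missing))
      stop(sprintf("external annotation missing columns: %s",
                   paste(missing, collapse = ", ")))
    return(tokens)
  }
  s <- tokens$surface
  low <- tolower(s)
  pos <- rep("NN", length(s))
  pos[grepl("^[0-9]+$", s)] <- "CD"
  pos[!grepl("[\\p{L}\\p{N}]", s, perl = TRUE)] <- "SYM"
  pos[s %in% c(".", ",", ":", ";")] <- s[s %in% c(".", ",", ":", ";")]
  closed <- c(the = "DT", a = "DT", an = "DT", this = "DT", these = "DT",
              of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN",
              with = "IN", from = "IN", to = "TO", "for" = "IN",
              and = "CC", or = "CC", but = "CC",
              is = "VBZ", are = "VBP", was = "VBD", were = "VBD",
              be = "VB", been = "VBN", not = "RB")
  hit <- low %in% names(closed)
  pos[hit] <- unname(closed[low[hit]])
  alpha <- grepl("^\\p{L}+$", s, perl = TRUE) & !hit
  pos[alpha & grepl("ly$", low)] <- "RB"
  pos[alpha & grepl("ing$", low) & nchar(s) > 4L] <- "VBG"
  pos[alpha & grepl("ed$", low) & nchar(s) > 3L] <- "VBD"
  pos[alpha & grepl("(ous|ive|ic|al|ary)$", low) & nchar(s) > 4L] <- "JJ"
  plural <- alpha & pos == "NN" & grepl("[^su]s$", low) & nchar(s) > 3L
  pos[plural] <- "NNS"
  lemma <- low
  for (i in which(plural)) {
    sing <- singularize_word(low[i])
    if (!is.na(sing)) lemma[i] <- sing
  }
  np <- pos %in% c("DT", "JJ", "CD") | startsWith(pos, "NN")
  chunk <- ifelse(np, "I-NP", "O")
  new_np <- np & !c(FALSE, np[-length(np)])
  # chunks must not cross sentence boundaries
  if (!is.null(tokens$sentence))
    new_np <- np & (new_np | c(TRUE, diff(tokens$sentence) != 0L))
  chunk[new_np] <- "B-NP"
  tokens$lemma <- lemma; tokens$pos <- pos; tokens$chunk <- chunk
  tokens
}

#' Orthographic features
#'
#' Fixed inventory of case/shape flags: exactly one of INITCAP, ALLCAPS,
#' ALLLOWER, MIXEDCASE for letter-bearing tokens, plus HASDIGIT, ALLDIGIT,
#' HASHYPHEN, SINGLECHAR, PUNCT and a collapsed word shape (caps -> A,
#' lower -> a, digit -> 0, other -> _, with runs collapsed).
#'
#' @param surface Non-empty string.
#' @return Character vector of feature strings (shape as `SHAPE=<shape>`).
#' @export
orthographic_features <- function(surface) {
  out <- character(0)
  has_alpha <- grepl("\\p{L}", surface, perl = TRUE)
  if (has_alpha) {
    if (grepl("^\\p{Lu}+$", surface, perl = TRUE)) out <- c(out, "ALLCAPS")
    else if (grepl("^\\p{Ll}+$", surface, perl = TRUE))
      out <- c(out, "ALLLOWER")
    else if (grepl("^\\p{Lu}\\p{Ll}*$", surface, perl = TRUE))
      out <- c(out, "INITCAP")
    else out <- c(out, "MIXEDCASE")
  }
  if (grepl("[0-9]", surface)) out <- c(out, "HASDIGIT")
  if (grepl("^[0-9]+$", surface)) out <- c(out, "ALLDIGIT")
  if (grepl("-", surface, fixed = TRUE)) out <- c(out, "HASHYPHEN")
  if (nchar(surface) == 1L) out <- c(out, "SINGLECHAR")
  if (!grepl("[\\p{L}\\p{N}]", surface, perl = TRUE)) out <- c(out, "PUNCT")
  c(out, paste0("SHAPE=", word_shape(surface)))
}

word_shape <- function(surface) {
  sh <- gsub("\\p{Lu}", "A", surface, perl = TRUE)
  sh <- gsub("\\p{Ll}", "a", sh, perl = TRUE)
  sh <- gsub("[0-9]", "0", sh)
  sh <- gsub("[^Aa0]", "_", sh)
  gsub("(.)\\1+", "\\1", sh)
}

#' Character n-gram features
#'
#' N-grams of each requested size over the surface padded with boundary
#' sentinels `^` and `$`, so prefix and suffix grams are distinguishable.
#' A surface shorter than `n - 2` yields the whole padded string as one
#' gram of that size.
#'
#' @param surface Token surface.
#' @param sizes Integer vector of n-gram sizes (default 2, 3, 4).
#' @return Character vector of `CG<n>=<gram>` feature strings.
#' @export
char_ngram_features <- function(surface, sizes = c(2L, 3L, 4L)) {
  if (!length(sizes)) return(character(0))
  padded <- paste0("^", surface, "$")
  np <- nchar(padded)
  unlist(lapply(sizes, function(n) {
    if (np <= n) return(paste0("CG", n, "=", padded))
    paste0("CG", n, "=", substring(padded, 1:(np - n + 1L), n:np))
  }), use.names = FALSE)
}

# value of family `fam` at offset `k` from focus, with <S> outside the
# sentence; `vals` is the per-token value vector of one sentence
offset_vals <- function(vals, k) {
  n <- length(vals)
  idx <- seq_len(n) + k
  out <- rep("<S>", n)
  ok <- idx >= 1L & idx <= n
  out[ok] <- vals[idx[ok]]
  out
}

#' Build the CRF feature representation of one sentence
#'
#' For each focus token: unigram features for the families surface (`W`,
#' truecased), normalized (`N`), lemma (`L`), POS (`P`) and chunk (`C`) at
#' every offset in the window; same-family bigrams at adjacent offset
#' pairs for the configured families; orthography and character n-grams at
#' the focus; dictionary features at every window offset; cluster prefix
#' features at offsets -1..+1; non-local features at the focus when
#' enabled.  Offsets outside the sentence contribute boundary features
#' (value `<S>`).
#'
#' @param sentence `data.frame` with columns `surface` (truecased, as the
#'   tagger sees it), `lemma`, `pos`, `chunk`, and optionally list columns
#'   `dict` (dictionary features per token, see [matches_to_features()]),
#'   `cluster` (cluster prefix features), `nonlocal`, and `local`
#'   (precomputed orthography/n-gram features; computed here when absent).
#' @param config A [feature_config()].
#' @return A list with one character vector of features per token
#'   (a feature sequence).
#' @export
build_feature_sequence <- function(sentence, config = feature_config()) {
  n <- nrow(sentence)
  if (!n) return(list())
  fam_vals <- list(W = sentence$surface,
                   N = normalize_surface(sentence$surface),
                   L = sentence$lemma, P = sentence$pos, C = sentence$chunk)
  w <- config$window
  offs <- seq.int(-w, w)
  parts <- vector("list", 0L)
  for (fam in names(fam_vals)) {
    for (k in offs)
      parts[[paste0(fam, k)]] <-
        paste0(fam, "[", k, "]=", offset_vals(fam_vals[[fam]], k))
    for (k in head(offs, -1L)) {
      if (!fam %in% config$bigram_families) next
      parts[[paste0(fam, k, "bg")]] <-
        paste0(fam, "[", k, "]|", fam, "[", k + 1L, "]=",
               offset_vals(fam_vals[[fam]], k), "|",
               offset_vals(fam_vals[[fam]], k + 1L))
    }
  }
  per_tok <- if (length(parts) == 1L) as.list(parts[[1L]]) else
    lapply(asplit(do.call(cbind, parts), 1L), as.vector)
  # focus-only families: orthography and character n-grams (precomputed
  # per unique surface when the caller supplies a `local` list column)
  local <- sentence$local
  if (is.null(local))
    local <- lapply(sentence$surface, function(s)
      c(orthographic_features(s),
        char_ngram_features(s, config$char_ngram_sizes)))
  for (i in seq_len(n)) per_tok[[i]] <- c(per_tok[[i]], local[[i]])
  if (config$use_dict && !is.null(sentence$dict)) {
    for (k in offs) {
      idx <- seq_len(n) + k
      for (i in seq_len(n)) {
        if (idx[i] >= 1L && idx[i] <= n && length(sentence$dict[[idx[i]]]))
          per_tok[[i]] <- c(per_tok[[i]],
                            sprintf("%s[%d]", sentence$dict[[idx[i]]], k))
      }
    }
  }
  if (config$use_clusters && !is.null(sentence$cluster)) {
    for (k in -1:1) {
      idx <- seq_len(n) + k
      for (i in seq_len(n)) {
        if (idx[i] >= 1L && idx[i] <= n &&
            length(sentence$cluster[[idx[i]]]))
          per_tok[[i]] <- c(per_tok[[i]],
                            sprintf("%s[%d]", sentence$cluster[[idx[i]]], k))
      }
    }
  }
  if (config$use_nonlocal && !is.null(sentence$nonlocal)) {
    for (i in seq_len(n))
      per_tok[[i]] <- c(per_tok[[i]], sentence$nonlocal[[i]])
  }
  lapply(per_tok, unname)
}
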