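#' Construct a lexicon
#'
#' A lexicon maps surface strings to non-empty sets of semantic-category
#' labels.  Surfaces are stored in a tokenization-aware canonical form
#' (tokens joined by single spaces, free-standing hyphens collapsed to
#' spaces, lowercased unless `case_sensitive`), so that "epithelial-cell"
#' and "epithelial cell" are the same entry under the aggressive
#' tokenization the tagger uses.
#'
#' @param surfaces Character vector of surface strings.
#' @param categories List of character vectors (one set per surface), or a
#'   character vector of comma-separated labels.
#' @param source Provenance tag: `"obo"`, `"majority"` or `"manual"`.
#' @param case_sensitive Match case-sensitively (default `FALSE`; matching
#'   normally runs on truecased text).
#' @return An object of class `"anatag_lexicon"`.
#' @export
lexicon <- function(surfaces = character(), categories = list(),
                    source = "manual", case_sensitive = FALSE) {
  if (is.character(categories)) categories <- strsplit(categories, ",")
  if (length(surfaces) != length(categories))
    stop("surfaces and categories must have equal length")
  if (any(!nzchar(surfaces))) stop("empty surface string in lexicon")
  if (any(lengths(categories) == 0L)) stop("empty category set in lexicon")
  keys <- canonical_surface(surfaces, case_sensitive)
  # merge duplicates by category union
  if (anyDuplicated(keys)) {
    categories <- lapply(split(categories, keys), function(cs)
      sort(unique(unlist(cs))))
    keys <- names(categories)
    categories <- unname(categories)
  } else {
    categories <- lapply(categories, function(cs) sort(unique(cs)))
  }
  structure(list(keys = keys, categories = categories, source = source,
                 case_sensitive = case_sensitive),
            class = "anatag_lexicon")
}

#' @export
print.anatag_lexicon <- function(x, ...) {
  cat(sprintf("<anatag_lexicon (%s): %d entries, %d categories%s>\n",
              x$source, length(x$keys),
              length(unique(unlist(x$categories))),
              if (x$case_sensitive) ", case-sensitive" else ""))
  invisible(x)
}

#' @export
length.anatag_lexicon <- function(x) length(x$keys)

#' Canonical surface form for lexicon matching
#'
#' @param s Character vector of surfaces (raw strings or pre-joined token
#'   spans).
#' @param case_sensitive Keep case?
#' @return Canonical keys.
#' @export
canonical_surface <- function(s, case_sensitive = FALSE) {
  # tokenize-and-join: alphanumeric runs and single symbols, single spaces
  s <- gsub("([^\\p{L}\\p{N}\\s])", " \\1 ", s, perl = TRUE)
  s <- gsub("\\s+", " ", trimws(s), perl = TRUE)
  s <- gsub(" - ", " ", s, fixed = TRUE)
  if (!case_sensitive) s <- tolower(s)
  s
}

#' Read / write a lexicon as TSV
#'
#' Format: `surface TAB category[,category...]` per line.
#' @param content TSV content.
#' @inheritParams lexicon
#' @return `read_lexicon`: an `"anatag_lexicon"`; `write_lexicon`: a string.
#' @export
read_lexicon <- function(content, source = "manual", case_sensitive = FALSE) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(lexicon(source = source,
                                     case_sensitive = case_sensitive))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 2L)) stop("lexicon lines must have 2 TSV fields")
  m <- do.call(rbind, f)
  lexicon(m[, 1], m[, 2], source = source, case_sensitive = case_sensitive)
}

#' @param lex An `"anatag_lexicon"` (for `write_lexicon`).
#' @rdname read_lexicon
#' @export
write_lexicon <- function(lex) {
  if (!length(lex$keys)) return("")
  paste0(paste(lex$keys, vapply(lex$categories, paste, character(1),
                                collapse = ","),
               sep = "\t", collapse = "\n"), "\n")
}

# ---------------------------------------------------------------- OBO ----

#' Parse an OBO flat file
#'
#' Reads `[Term]` stanzas from OBO 1.2/1.4 content: term id, name, synonym
#' strings (the quoted part only), `is_a` targets (text after any "!"
#' comment stripped) and the obsolete flag.  The is-a graph must be acyclic.
#'
#' @param content OBO flat-file content.
#' @return An object of class `"obo_graph"`: `terms` is a named list with
#'   elements `name`, `synonyms`, `is_a`, `obsolete`; `roots` are ids with
#'   no is-a parent.
#' @export
parse_obo <- function(content) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (is.null(cur)) return(terms)
    if (is.null(cur$id)) stop("OBO [Term] stanza without id")
    terms[[cur$id]] <- list(name = cur$name %||% NA_character_,
                            synonyms = cur$synonyms,
                            is_a = cur$is_a, obsolete = cur$obsolete)
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("^\\s+|\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(synonyms = character(), is_a = character(),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { terms <- flush(cur, terms); cur <- NULL
                             in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-zA-Z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "synonym") {
      q <- regmatches(val, regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"", val))[[1]]
      if (length(q) == 2L) cur$synonyms <- c(cur$synonyms,
                                             gsub("\\\\(.)", "\\1", q[2]))
    } else if (key == "is_a") {
      cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", val)))
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  # drop is_a edges to unknown ids (partial extracts), then check acyclicity
  for (id in ids) terms[[id]]$is_a <-
    terms[[id]]$is_a[terms[[id]]$is_a %in% ids]
  check_obo_acyclic(terms)
  roots <- ids[vapply(terms, function(t) length(t$is_a) == 0L, logical(1))]
  structure(list(terms = terms, roots = roots), class = "obo_graph")
}

check_obo_acyclic <- function(terms) {
  color <- setNames(integer(length(terms)), names(terms))  # 0 new 1 open 2 done
  stack_trace <- character(0)
  visit <- function(id) {
    if (color[[id]] == 1L)
      stop(sprintf("cycle in is_a relations: %s",
                   paste(c(stack_trace, id), collapse = " -> ")))
    if (color[[id]] == 2L) return(invisible())
    color[[id]] <<- 1L
    stack_trace <<- c(stack_trace, id)
    for (p in terms[[id]]$is_a) visit(p)
    stack_trace <<- stack_trace[-length(stack_trace)]
    color[[id]] <<- 2L
  }
  for (id in names(terms)) visit(id)
  invisible()
}

#' @export
print.obo_graph <- function(x, ...) {
  cat(sprintf("<obo_graph: %d terms, %d roots, %d obsolete>\n",
              length(x$terms), length(x$roots),
              sum(vapply(x$terms, `[[`, logical(1), "obsolete"))))
  invisible(x)
}

obo_ancestors <- function(graph) {
  # transitive is_a closure (including self), memoized over a topological walk
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- id
    for (p in graph$terms[[id]]$is_a) res <- c(res, anc(p))
    res <- unique(res)
    memo[[id]] <- res
    res
  }
  setNames(lapply(names(graph$terms), anc), names(graph$terms))
}

#' Compile a lexicon from an OBO ontology
#'
#' Every non-obsolete term contributes its name and synonyms (plus their
#' [expand_variants()] expansions) as surfaces, mapped to the union of
#' upper-level category labels reachable from the term by transitive is-a
#' ascent.  Terms reaching no mapped ancestor get category `"other"`.  To
#' bound feature dimensionality, only the `top_k` most frequent categories
#' (by number of surface entries) are kept; the rest are relabeled
#' `"other"`.
#'
#' @param graph An `"obo_graph"`.
#' @param upper_map Named character vector: term id -> category label, for
#'   the designated upper-level terms.
#' @param top_k Number of category labels kept before collapsing to
#'   `"other"` (default 100).
#' @param expand Apply [expand_variants()] to each surface (default `TRUE`).
#' @return An `"anatag_lexicon"` with `source = "obo"`.
#' @export
compile_obo_lexicon <- function(graph, upper_map, top_k = 100L,
                                expand = TRUE) {
  if (top_k < 1L) stop("top_k must be >= 1")
  anc <- obo_ancestors(graph)
  surfaces <- character(); cats <- list()
  for (id in names(graph$terms)) {
    t <- graph$terms[[id]]
    if (t$obsolete) next
    labels <- unname(upper_map[intersect(anc[[id]], names(upper_map))])
    labels <- unique(labels[!is.na(labels)])
    if (!length(labels)) labels <- "other"
    surf <- c(if (!is.na(t$name)) t$name, t$synonyms)
    surf <- surf[nzchar(surf)]
    if (expand && length(surf))
      surf <- unique(unlist(lapply(surf, expand_variants)))
    for (s in surf) {
      surfaces <- c(surfaces, s)
      cats[[length(cats) + 1L]] <- labels
    }
  }
  lex <- lexicon(surfaces, cats, source = "obo")
  cap_lexicon_categories(lex, top_k)
}

cap_lexicon_categories <- function(lex, top_k) {
  freq <- table(unlist(lex$categories))
  freq <- freq[names(freq) != "other"]
  if (length(freq) <= top_k) return(lex)
  ord <- order(-as.integer(freq), names(freq))
  keep <- names(freq)[ord][seq_len(top_k)]
  lex$categories <- lapply(lex$categories, function(cs) {
    cs[!cs %in% keep] <- "other"
    sort(unique(cs))
  })
  lex
}

#' Generate surface-form variants
#'
#' A documented, rule-based stand-in for full lexical variant generation:
#' adds the lowercased form, a regular plural/singular counterpart of the
#' head (last) word, and hyphen/space alternation for multiword entries.
#' The input surface is always included.
#'
#' @param surface Non-empty string.
#' @return Character vector of unique variants.
#' @export
expand_variants <- function(surface) {
  if (!nzchar(surface)) stop("empty surface")
  out <- c(surface, tolower(surface))
  for (base in unique(out)) {
    words <- strsplit(base, " ", fixed = TRUE)[[1]]
    h <- words[length(words)]
    for (v in c(pluralize_word(h), singularize_word(h))) {
      if (!is.na(v) && v != h)
        out <- c(out, paste(c(words[-length(words)], v), collapse = " "))
    }
  }
  multi <- out[grepl(" ", out, fixed = TRUE)]
  out <- c(out, gsub(" ", "-", multi, fixed = TRUE))
  hyph <- out[grepl("-", out, fixed = TRUE)]
  out <- c(out, gsub("-", " ", hyph, fixed = TRUE))
  unique(out)
}

pluralize_word <- function(w) {
  if (grepl("[^aeiouAEIOU]y$", w)) return(sub("y$", "ies", w))
  if (grepl("(s|x|z|ch|sh)$", w)) return(paste0(w, "es"))
  if (grepl("[[:alpha:]]$", w)) return(paste0(w, "s"))
  NA_character_
}

singularize_word <- function(w) {
  if (grepl("ies$", w) && nchar(w) > 4L) return(sub("ies$", "y", w))
  if (grepl("(ses|xes|zes|ches|shes)$", w)) return(sub("es$", "", w))
  if (grepl("[^su]s$", w)) return(sub("s$", "", w))
  NA_character_
}

# ----------------------------------------------------- majority filter ----

#' Compile a lexicon from string-type occurrence records
#'
#' Given one record per observed occurrence of a string (each carrying the
#' set of semantic types assigned on that occasion), keeps for each string
#' the types associated with it in at least `threshold` of its occurrences
#' (boundary inclusive: a type seen in exactly half the occurrences
#' survives at the default threshold).  Strings with no surviving type are
#' dropped.
#'
#' @param records `data.frame(string, types)` with `types` either a list
#'   column of character vectors or comma-separated strings; one row per
#'   occurrence.
#' @param threshold Minimum fraction of occurrences (default 0.5).
#' @param relevant_types Optional character vector; other types are removed
#'   from the occurrence sets before counting (occurrences still count
#'   toward the denominator).
#' @return An `"anatag_lexicon"` with `source = "majority"`.
#' @export
compile_majority_lexicon <- function(records, threshold = 0.5,
                                     relevant_types = NULL) {
  if (!nrow(records)) return(lexicon(source = "majority"))
  types <- records$types
  if (is.character(types)) types <- strsplit(types, ",")
  types <- lapply(types, unique)
  if (!is.null(relevant_types))
    types <- lapply(types, intersect, relevant_types)
  surfaces <- character(); cats <- list()
  for (s in unique(records$string)) {
    idx <- which(records$string == s)
    n <- length(idx)
    cnt <- table(unlist(types[idx]))
    keep <- names(cnt)[as.integer(cnt) / n >= threshold]
    if (length(keep)) {
      surfaces <- c(surfaces, s)
      cats[[length(cats) + 1L]] <- keep
    }
  }
  lexicon(surfaces, cats, source = "majority")
}

# ---------------------------------------------------- dictionary tagging --

#' Tag token sequences against a lexicon
#'
#' Candidate spans are token runs (within one sentence, at most `max_span`
#' tokens) whose canonical joined surface is a lexicon entry.  Three modes:
#' `"all"` returns every candidate (so relevant embedded terms are never
#' blocked by longer non-relevant ones), `"longest"` applies greedy
#' leftmost-longest matching (repeatedly take the longest candidate at the
#' smallest untagged start index and skip past it), `"token"` keeps only
#' single-token candidates.  The optional POS filter drops candidates
#' containing no token whose POS tag starts with "NN".
#'
#' @param tokens `data.frame` with at least `surface` (and `sentence`;
#'   `pos` when `pos_filter = "require_nn"`).
#' @param lex An `"anatag_lexicon"`.
#' @param mode `"all"`, `"longest"` or `"token"`.
#' @param pos_filter `"none"` or `"require_nn"`.
#' @param max_span Maximum candidate length in tokens (default 8).
#' @return `data.frame(start, end, categories)` with 1-based half-open
#'   token-index spans (`start < end`) and a list column of category sets.
#' @export
tag_dictionary <- function(tokens, lex, mode = c("longest", "all", "token"),
                           pos_filter = c("none", "require_nn"),
                           max_span = 8L) {
  mode <- match.arg(mode); pos_filter <- match.arg(pos_filter)
  if (max_span < 1L) stop("max_span must be >= 1")
  n <- nrow(tokens)
  empty <- data.frame(start = integer(), end = integer())
  empty$categories <- list()
  if (!n || !length(lex$keys)) return(empty)
  sent <- tokens$sentence %||% rep(1L, n)
  surf <- if (lex$case_sensitive) tokens$surface else tolower(tokens$surface)
  is_nn <- if (pos_filter == "require_nn") startsWith(tokens$pos, "NN")
  starts <- integer(); ends <- integer(); key_idx <- integer()
  max_l <- if (mode == "token") 1L else as.integer(max_span)
  joined <- surf  # joined[i] holds surface of span i..i+l-1 at current l
  has_nn <- if (pos_filter == "require_nn") is_nn
  for (l in seq_len(max_l)) {
    if (l > n) break
    if (l > 1L) {
      idx <- seq_len(n - l + 1L)
      joined <- paste(joined[idx], surf[idx + l - 1L])
      if (pos_filter == "require_nn")
        has_nn <- has_nn[idx] | is_nn[idx + l - 1L]
    }
    idx <- seq_len(n - l + 1L)
    ok <- sent[idx] == sent[idx + l - 1L]
    if (pos_filter == "require_nn") ok <- ok & has_nn
    cand <- gsub(" - ", " ", joined, fixed = TRUE)
    hit <- match(cand, lex$keys)
    sel <- which(ok & !is.na(hit))
    if (length(sel)) {
      starts <- c(starts, sel); ends <- c(ends, sel + l)
      key_idx <- c(key_idx, hit[sel])
    }
  }
  if (!length(starts)) return(empty)
  out <- data.frame(start = starts, end = ends)
  out$categories <- lex$categories[key_idx]
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  rownames(out) <- NULL
  if (mode == "longest") {
    keep <- logical(nrow(out)); pos <- 1L
    for (i in seq_len(nrow(out))) {
      if (out$start[i] >= pos) { keep[i] <- TRUE; pos <- out$end[i] }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Convert dictionary matches to per-token features
#'
#' Each matched token receives `DICT-B-<cat>` (first token of the span) or
#' `DICT-I-<cat>` features; overlapping matches contribute the union.
#'
#' @param matches Output of [tag_dictionary()].
#' @param n_tokens Number of tokens.
#' @return List of character vectors, one per token.
#' @export
matches_to_features <- function(matches, n_tokens) {
  feats <- rep(list(character(0)), n_tokens)
  for (i in seq_len(nrow(matches))) {
    s <- matches$start[i]; e <- matches$end[i]
    cats <- matches$categories[[i]]
    feats[[s]] <- c(feats[[s]], paste0("DICT-B-", cats))
    for (j in seq(s + 1L, length.out = e - s - 1L))
      feats[[j]] <- c(feats[[j]], paste0("DICT-I-", cats))
  }
  lapply(feats, function(f) sort(unique(f)))
}

#' Read string-type occurrence records from TSV
#'
#' One line per observed occurrence: `surface TAB type[,type...]` — the
#' input format of [compile_majority_lexicon()].
#'
#' @param content TSV content.
#' @return `data.frame(string, types)` with comma-separated type sets.
#' @export
read_occurrences <- function(content) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(string = character(), types = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 2L))
    stop("occurrence lines must have 2 TSV fields")
  m <- do.call(rbind, f)
  data.frame(string = m[, 1], types = m[, 2], stringsAsFactors = FALSE)
}
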