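default_abbreviations <- c(
  "e.g.", "i.e.", "etc.", "cf.", "vs.", "ca.", "al.", "et al.", "Fig.",
  "Figs.", "Eq.", "Ref.", "Refs.", "no.", "No.", "approx.", "resp.",
  "Dr.", "Prof.", "St.", "Mr.", "Ms.", "Jr.", "Sr.", "E.", "S.", "B.",
  "spp.", "sp.", "var.", "wt.", "vol.", "pp.")

#' Segment text into sentences
#'
#' Rule-based splitter: a sentence ends at sentence-final punctuation
#' (`.`, `!`, `?`, optionally followed by closing quotes/brackets) that is
#' followed by whitespace and an uppercase letter or digit, unless the
#' punctuation terminates a known abbreviation.  Blank lines always force a
#' boundary, so headings become their own "sentences".  Spans cover all
#' non-whitespace text.
#'
#' Pre-segmented input can bypass this entirely via [read_conll()].
#'
#' @param text Input text.
#' @param abbreviations Character vector of abbreviation strings (each
#'   ending in "."); a candidate boundary is suppressed when the text up to
#'   and including the period ends with one of them.
#' @return `data.frame(start, end)` of 0-based half-open sentence spans.
#' @export
split_sentences <- function(text, abbreviations = default_abbreviations) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  chars <- strsplit(text, "")[[1]]
  is_ws <- grepl("^\\s$", chars)
  brk <- logical(n)   # brk[i]: segment boundary after character i
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      j <- i + 1L
      while (j <= n && chars[j] %in% c("\"", "'", ")", "]")) j <- j + 1L
      if (j > n || is_ws[j]) {
        k <- j
        while (k <= n && is_ws[k]) k <- k + 1L
        next_ok <- k > n || grepl("^[\\p{Lu}\\p{N}]$", chars[k], perl = TRUE)
        if (next_ok && !(ch == "." &&
                         ends_with_abbrev(substr(text, 1L, i), abbreviations)))
          brk[j - 1L] <- TRUE
      }
      i <- j
    } else if (ch == "\n") {
      j <- i + 1L
      while (j <= n && chars[j] %in% c(" ", "\t")) j <- j + 1L
      if (j <= n && chars[j] == "\n") { brk[i] <- TRUE; i <- j + 1L }
      else i <- i + 1L
    } else i <- i + 1L
  }
  brk[n] <- TRUE
  out_s <- integer(); out_e <- integer()
  seg_start <- 1L
  for (i in seq_len(n)) {
    if (brk[i]) {
      s <- seg_start; e <- i
      while (s <= e && is_ws[s]) s <- s + 1L
      while (e >= s && is_ws[e]) e <- e - 1L
      if (s <= e) { out_s <- c(out_s, s - 1L); out_e <- c(out_e, e) }
      seg_start <- i + 1L
    }
  }
  data.frame(start = out_s, end = out_e)
}

ends_with_abbrev <- function(prefix, abbreviations) {
  for (a in abbreviations) {
    la <- nchar(a)
    if (nchar(prefix) >= la &&
        substr(prefix, nchar(prefix) - la + 1L, nchar(prefix)) == a) {
      # require word boundary (or string start) before the abbreviation
      if (nchar(prefix) == la) return(TRUE)
      before <- substr(prefix, nchar(prefix) - la, nchar(prefix) - la)
      if (grepl("[^\\p{L}\\p{N}]", before, perl = TRUE)) return(TRUE)
    }
  }
  FALSE
}

#' Aggressive tokenization
#'
#' Preserves contiguous runs of alphanumeric characters (Unicode letters
#' and digits) as tokens and makes every other non-whitespace character its
#' own single-character token, so that mention boundaries inside
#' constructions such as "platelet-derived" fall on token boundaries.
#'
#' @param text Document text.
#' @param span Optional `c(start, end)` 0-based half-open span (default:
#'   whole text).
#' @param sentence_index Integer stored in the `sentence` column.
#' @return `data.frame(surface, start, end, sentence)` with 0-based
#'   half-open character offsets into `text`.
#' @export
tokenize <- function(text, span = NULL, sentence_index = 1L) {
  if (is.null(span)) span <- c(0L, nchar(text))
  seg <- substr0(text, span[1], span[2])
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), sentence = integer())
  if (!nchar(seg)) return(empty)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", seg, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  start <- span[1] + as.integer(m) - 1L
  data.frame(surface = substring(seg, m, m + len - 1L),
             start = start, end = start + len,
             sentence = sentence_index)
}

#' Segment and tokenize a document in place
#'
#' @param doc An `"anatag_document"`.
#' @param abbreviations Passed to [split_sentences()].
#' @return The document with `sentences` and `tokens` filled in.
#' @export
segment_document <- function(doc, abbreviations = default_abbreviations) {
  sp <- split_sentences(doc$text, abbreviations)
  toks <- lapply(seq_len(nrow(sp)), function(i)
    tokenize(doc$text, c(sp$start[i], sp$end[i]), i))
  doc$sentences <- sp
  doc$tokens <- if (length(toks)) do.call(rbind, toks) else tokenize("")
  doc
}

#' Train a unigram truecasing model
#'
#' Counts cased variants of each word in a background corpus and records,
#' for every lowercased key with total count at least `min_count`, the most
#' frequent cased form.  Ties go to the all-lowercase form, then
#' lexicographically.  Sentence-initial tokens should be excluded from the
#' stream by the caller (see [truecase_token_stream()]), since their
#' capitalization is conventional rather than lexical.
#'
#' @param token_stream Character vector of token surfaces.
#' @param min_count Minimum total occurrences of a key to trust (default 5).
#' @return An object of class `"case_model"`.
#' @export
train_truecaser <- function(token_stream, min_count = 5L) {
  token_stream <- token_stream[nzchar(token_stream)]
  if (!length(token_stream))
    return(structure(list(dominant = character(0), counts = integer(0),
                          min_count = min_count), class = "case_model"))
  counts <- table(token_stream)
  forms <- names(counts)
  keys <- tolower(forms)
  total <- tapply(as.integer(counts), keys, sum)
  keep_keys <- names(total)[total >= min_count]
  dominant <- vapply(keep_keys, function(k) {
    idx <- which(keys == k)
    cand <- forms[idx]; cnt <- as.integer(counts[idx])
    best <- cand[cnt == max(cnt)]
    if (k %in% best) k else sort(best)[1]
  }, character(1))
  structure(list(dominant = dominant,
                 counts = setNames(as.integer(counts), forms),
                 min_count = min_count),
            class = "case_model")
}

#' @export
print.case_model <- function(x, ...) {
  cat(sprintf("<case_model: %d keys (min_count=%d)>\n",
              length(x$dominant), x$min_count))
  invisible(x)
}

#' Extract a truecaser training stream from tokenized sentences
#'
#' Drops sentence-initial tokens to avoid capitalization bias.
#'
#' @param sentences List of character vectors (token surfaces per sentence).
#' @return Character vector of surfaces.
#' @export
truecase_token_stream <- function(sentences) {
  unlist(lapply(sentences, function(s) if (length(s) > 1L) s[-1L] else
    character(0)), use.names = FALSE)
}

is_capitalized <- function(w) grepl("^\\p{Lu}", w, perl = TRUE)

sentence_case_context <- function(surfaces,
                                  title_frac = 0.75, title_min_tokens = 3L,
                                  upper_frac = 0.90, upper_min_tokens = 2L) {
  alpha <- grepl("\\p{L}", surfaces, perl = TRUE)
  chars <- paste0(surfaces[alpha], collapse = "")
  n_up <- nchar(gsub("[^\\p{Lu}]", "", chars, perl = TRUE))
  n_alpha <- nchar(gsub("[^\\p{L}]", "", chars, perl = TRUE))
  if (sum(alpha) >= upper_min_tokens && n_alpha > 0L &&
      n_up / n_alpha >= upper_frac) return("allupper")
  long <- alpha & nchar(surfaces) > 3L
  if (sum(long) >= title_min_tokens &&
      mean(is_capitalized(surfaces[long])) >= title_frac) return("title")
  "plain"
}

#' Restore neutral case with a unigram model
#'
#' Rewrites a token to its model-dominant form only in the three contexts
#' where orthographic convention distorts case: (i) sentence-initial
#' capitalized words, (ii) Title Case sentences (headings), and (iii)
#' ALL-UPPER sentences.  Tokens absent from the model, or outside those
#' contexts, are untouched; character offsets are never changed (truecasing
#' affects the feature-visible surface only, never the document text).
#'
#' @param sentences List of character vectors of token surfaces.
#' @param model A `"case_model"` from [train_truecaser()].
#' @return List of character vectors of (possibly rewritten) surfaces.
#' @export
truecase <- function(sentences, model) {
  lapply(sentences, function(s) {
    if (!length(s)) return(s)
    ctx <- sentence_case_context(s)
    rewrite <- if (ctx == "plain") {
      c(is_capitalized(s[1]), rep(FALSE, length(s) - 1L))
    } else rep(TRUE, length(s))
    key <- tolower(s)
    hit <- rewrite & key %in% names(model$dominant)
    s[hit] <- unname(model$dominant[key[hit]])
    s
  })
}

#' Serialize / read a case model as TSV
#'
#' Format: `lowercased_key TAB dominant_form TAB count` per line.
#'
#' @param model A `"case_model"`.
#' @return For `write_case_model`, the TSV content as one string.
#' @export
write_case_model <- function(model) {
  if (!length(model$dominant)) return("")
  keys <- names(model$dominant)
  total <- vapply(keys, function(k)
    sum(model$counts[tolower(names(model$counts)) == k]), integer(1))
  paste0(paste(keys, unname(model$dominant), total, sep = "\t",
               collapse = "\n"), "\n")
}

#' @param content TSV content (for `read_case_model`).
#' @param min_count Threshold recorded on the restored model.
#' @rdname write_case_model
#' @export
read_case_model <- function(content, min_count = 5L) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(structure(list(dominant = character(0), counts = integer(0),
                          min_count = min_count), class = "case_model"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3L)) stop("case model lines must have 3 TSV fields")
  m <- do.call(rbind, f)
  structure(list(dominant = setNames(m[, 2], m[, 1]),
                 counts = setNames(as.integer(m[, 3]), m[, 2]),
                 min_count = min_count),
            class = "case_model")
}
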