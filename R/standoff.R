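#' Construct a mention table
#'
#' Mentions are contiguous, non-overlapping character spans with exactly one
#' entity type.  Offsets are 0-based, half-open code-point offsets into the
#' document text, following the BioNLP Shared Task standoff convention.
#'
#' @param start,end Integer vectors of span offsets, `0 <= start < end`.
#' @param type Character vector of entity type labels.
#' @param text Covered strings (optional; filled from `doc_text` if given).
#' @param doc_text Document text used to validate/fill the `text` column.
#' @return A `data.frame` with columns `start`, `end`, `type`, `text`,
#'   sorted by `start`.
#' @export
mentions <- function(start = integer(), end = integer(),
                     type = character(), text = NULL, doc_text = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  type <- as.character(type)
  if (length(start) != length(end) || length(start) != length(type))
    stop("start, end and type must have equal length")
  if (any(start < 0L) || any(end <= start))
    stop("mention spans must satisfy 0 <= start < end")
  if (!is.null(doc_text)) {
    if (any(end > nchar(doc_text)))
      stop("mention end offset beyond document text")
    covered <- substr0(doc_text, start, end)
    if (is.null(text)) text <- covered
    else if (any(text != covered)) {
      i <- which(text != covered)[1]
      stop(sprintf("mention text mismatch at [%d,%d): expected %s, found %s",
                   start[i], end[i], dQuote(text[i]), dQuote(covered[i])))
    }
  }
  if (is.null(text)) text <- rep(NA_character_, length(start))
  m <- data.frame(start = start, end = end, type = type,
                  text = as.character(text), stringsAsFactors = FALSE)
  m <- m[order(m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) > 1L) {
    ov <- which(m$start[-1L] < m$end[-nrow(m)])
    if (length(ov))
      stop(sprintf("overlapping mentions: [%d,%d) %s and [%d,%d) %s",
                   m$start[ov[1]], m$end[ov[1]], m$type[ov[1]],
                   m$start[ov[1] + 1L], m$end[ov[1] + 1L], m$type[ov[1] + 1L]))
  }
  m
}

#' Construct a document
#'
#' A document bundles raw text with its gold or predicted mention set and,
#' once segmented, sentence spans and tokens.
#'
#' @param text Full document string (UTF-8).
#' @param doc_id Identifier.
#' @param mentions Mention table as produced by [mentions()], or `NULL`.
#' @param sentences Optional `data.frame(start, end)` of sentence spans.
#' @param tokens Optional token table (see [tokenize()]).
#' @return An object of class `"anatag_document"`.
#' @export
document <- function(text, doc_id = "doc", mentions = NULL,
                     sentences = NULL, tokens = NULL) {
  if (is.null(mentions)) mentions <- anatag::mentions()
  if (nrow(mentions) && max(mentions$end) > nchar(text))
    stop("mention offsets exceed document length")
  structure(list(doc_id = doc_id, text = text, mentions = mentions,
                 sentences = sentences, tokens = tokens),
            class = "anatag_document")
}

#' @export
print.anatag_document <- function(x, ...) {
  cat(sprintf("<anatag_document '%s': %d chars, %d mentions", x$doc_id,
              nchar(x$text), nrow(x$mentions)))
  if (!is.null(x$tokens))
    cat(sprintf(", %d tokens / %d sentences",
                nrow(x$tokens), length(unique(x$tokens$sentence))))
  cat(">\n")
  invisible(x)
}

#' Read a standoff-annotated document
#'
#' Parses BioNLP Shared Task-style standoff: each entity is one line
#' `T<id> TAB type SPACE start SPACE end TAB text`.  Offsets must index the
#' text, the text column must equal the covered substring, and mentions must
#' be pairwise disjoint; violations are errors naming the offending line.
#' Non-"T" lines (relations, events, notes) are rejected.
#'
#' @param txt_content Document text.
#' @param ann_content Standoff annotation content ("" for no mentions).
#' @param doc_id Identifier for the resulting document.
#' @return An `"anatag_document"` with mentions sorted by start offset.
#' @export
read_standoff <- function(txt_content, ann_content = "", doc_id = "doc") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (!n) return(document(txt_content, doc_id))
  start <- integer(n); end <- integer(n)
  type <- character(n); text <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L || !grepl("^T[0-9]+$", fields[1]))
      stop(sprintf("malformed standoff line %d: %s", i, dQuote(lines[i])))
    span <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
    if (length(span) != 3L || anyNA(suppressWarnings(as.integer(span[2:3]))))
      stop(sprintf("malformed type/span field on line %d: %s",
                   i, dQuote(fields[2])))
    type[i] <- span[1]
    start[i] <- as.integer(span[2]); end[i] <- as.integer(span[3])
    text[i] <- fields[3]
    if (start[i] < 0L || end[i] <= start[i] || end[i] > nchar(txt_content))
      stop(sprintf("offsets out of range on line %d: %d %d (text length %d)",
                   i, start[i], end[i], nchar(txt_content)))
  }
  m <- mentions(start, end, type, text, doc_text = txt_content)
  document(txt_content, doc_id, mentions = m)
}

#' Serialize a document's mentions to standoff format
#'
#' Inverse of [read_standoff()]: mentions are emitted in start order,
#' renumbered `T1..Tn`.
#'
#' @param doc An `"anatag_document"`.
#' @return A single string; `""` for a document without mentions.
#' @export
write_standoff <- function(doc) {
  m <- doc$mentions
  if (!nrow(m)) return("")
  m <- m[order(m$start, m$end), , drop = FALSE]
  txt <- m$text
  if (anyNA(txt)) {
    na <- is.na(txt)
    txt[na] <- substr0(doc$text, m$start[na], m$end[na])
  }
  paste0(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(m)), m$type,
                 m$start, m$end, txt), collapse = "\n") |> paste0("\n")
}

conll_cols <- c("surface", "start", "end", "lemma", "pos", "chunk")

#' Read sentences from CoNLL-style TSV
#'
#' Blank-line-separated sentence blocks; one token per line with columns
#' surface, start, end, lemma, POS, chunk and optionally a gold label.
#' This is the interchange format for supplying externally produced
#' morphosyntactic annotation (and pre-split sentences) to the tagger.
#'
#' @param content File content as a single string.
#' @return List of sentence `data.frame`s with the columns above; a `label`
#'   column is present only when the input has seven columns.
#' @export
read_conll <- function(content) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)]))
  sentences <- list()
  ncol_seen <- NA_integer_
  for (g in split(seq_along(lines), grp)) {
    g <- g[!blank[g]]
    if (!length(g)) next
    fields <- strsplit(lines[g], "\t", fixed = TRUE)
    nc <- lengths(fields)
    if (any(nc != nc[1]))
      stop(sprintf("ragged CoNLL columns at line %d", g[which(nc != nc[1])[1]]))
    if (!nc[1] %in% c(6L, 7L))
      stop(sprintf("expected 6 or 7 CoNLL columns, found %d at line %d",
                   nc[1], g[1]))
    if (!is.na(ncol_seen) && nc[1] != ncol_seen)
      stop(sprintf("inconsistent column count at line %d", g[1]))
    ncol_seen <- nc[1]
    m <- do.call(rbind, fields)
    s <- data.frame(surface = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), lemma = m[, 4], pos = m[, 5],
                    chunk = m[, 6], stringsAsFactors = FALSE)
    if (ncol_seen == 7L) s$label <- m[, 7]
    sentences[[length(sentences) + 1L]] <- s
  }
  sentences
}

#' Write sentences to CoNLL-style TSV
#'
#' Inverse of [read_conll()]; round-trips the column set present.
#'
#' @param sentences List of sentence `data.frame`s.
#' @return File content as a single string.
#' @export
write_conll <- function(sentences) {
  if (!length(sentences)) return("")
  blocks <- vapply(sentences, function(s) {
    cols <- c(conll_cols, if ("label" %in% names(s)) "label")
    vals <- lapply(cols, function(cn) as.character(s[[cn]]))
    if (any(grepl("\t", unlist(vals), fixed = TRUE)))
      stop("TAB is a reserved delimiter in CoNLL fields")
    paste0(do.call(paste, c(vals, sep = "\t")), collapse = "\n")
  }, character(1))
  paste0(paste0(blocks, collapse = "\n\n"), "\n")
}
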