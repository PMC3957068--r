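#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the tagger exploits in
#' real biomedical text: typed entity mentions embedded in running text at
#' about 26 mentions per 1000 words, document-level sense consistency of
#' ambiguous surfaces (one sense per discourse) with type-specific context
#' cues, a partially covering feature lexicon, and case distortion at
#' sentence starts and in headers.  Filler and entity vocabularies are
#' synthetic strings, so no external resource is ever required.
#'
#' @param seed Master seed; the whole module is deterministic given it.
#' @param n_docs Number of documents.
#' @param doc_length_mean,doc_length_sd Body length in tokens (normal,
#'   truncated below at 80).
#' @param n_types Number of entity types (up to 12; the canonical
#'   anatomical names from [anatag_types()] are used).
#' @param lexicon_size Number of entity surfaces in the generating lexicon.
#' @param multiword_fraction Fraction of surfaces that are 2-3 token
#'   phrases.
#' @param mention_density Planted mentions per 1000 body tokens
#'   (default 26).
#' @param ambiguity_rate Fraction of surfaces valid under two types.
#' @param context_cue_strength Probability that a type-specific cue word
#'   immediately precedes a mention; at least one occurrence per (document,
#'   ambiguous surface) is always cued.
#' @param dict_coverage Fraction of entity surfaces present in the feature
#'   lexicon handed to the tagger.
#' @param surfaces_per_doc Entity surfaces active per document (documents
#'   reuse a small surface pool, giving the within-document repetition that
#'   non-local features exploit).
#' @param background_vocab Size of the Zipf-distributed filler vocabulary.
#' @param case_sentence_initial,case_title_rate,case_allcaps_rate Case
#'   distortion rates for [distort_case()]: probability of capitalizing a
#'   sentence-initial token, and of rendering a header in Title Case or
#'   ALL-UPPER.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_docs = 10L, doc_length_mean = 600,
                         doc_length_sd = 100, n_types = 12L,
                         lexicon_size = 400L, multiword_fraction = 0.3,
                         mention_density = 26, ambiguity_rate = 0.3,
                         context_cue_strength = 0.9, dict_coverage = 0.7,
                         surfaces_per_doc = 8L, background_vocab = 2000L,
                         case_sentence_initial = 1, case_title_rate = 0.5,
                         case_allcaps_rate = 0.3) {
  rates <- c(multiword_fraction, ambiguity_rate, context_cue_strength,
             dict_coverage, case_sentence_initial, case_title_rate,
             case_allcaps_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (mention_density < 0) stop("mention_density must be >= 0")
  if (n_types < 1L || n_types > 12L) stop("n_types must be in 1..12")
  if (lexicon_size < n_types) stop("lexicon_size must be >= n_types")
  structure(as.list(environment()), class = "synth_config")
}

# unique pronounceable-ish word strings
synth_words <- function(n, min_syll = 2L) {
  on <- c("b", "br", "c", "cr", "d", "dr", "f", "fl", "g", "gl", "h", "k",
          "l", "m", "n", "p", "pl", "pr", "r", "s", "st", "t", "tr", "v",
          "z", "th", "sk")
  vo <- c("a", "e", "i", "o", "u", "ai", "or", "ul", "en")
  out <- character(0)
  while (length(out) < n) {
    k <- (n - length(out)) * 2L
    syll <- function() paste0(sample(on, k, TRUE), sample(vo, k, TRUE))
    w <- paste0(syll(), syll(),
                ifelse(runif(k) < 0.45, paste0(syll()), ""))
    if (min_syll > 2L) w <- paste0(w, syll())
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a typed entity lexicon (and supporting vocabularies)
#'
#' Creates `lexicon_size` unique entity surfaces (a `multiword_fraction`
#' of them 2-3 token phrases), assigns each one type — or two, for an
#' `ambiguity_rate` fraction —, draws per-type context cue words, and a
#' disjoint Zipf-ranked background vocabulary with gold POS tags and
#' canonical case (a few percent of filler words are acronym-like
#' ALL-CAPS or Capitalized, which truecasing must preserve).
#'
#' @param config A [synth_config()].
#' @return An object of class `"synth_lexicon"`.
#' @export
generate_lexicon <- function(config) {
  set.seed(config$seed)
  types <- head(anatag_types(), config$n_types)
  n_multi <- round(config$lexicon_size * config$multiword_fraction)
  n_single <- config$lexicon_size - n_multi
  n_cues <- 3L * config$n_types
  n_mods <- 40L
  pool <- synth_words(n_single + n_multi + n_cues + n_mods +
                        config$background_vocab)
  stems <- pool[seq_len(n_single)]
  heads <- pool[n_single + seq_len(n_multi)]
  cue_words <- pool[n_single + n_multi + seq_len(n_cues)]
  mods <- pool[n_single + n_multi + n_cues + seq_len(n_mods)]
  bg <- pool[n_single + n_multi + n_cues + n_mods +
               seq_len(config$background_vocab)]
  multi <- if (n_multi) paste(sample(mods, n_multi, TRUE),
                              ifelse(runif(n_multi) < 0.3,
                                     paste(sample(mods, n_multi, TRUE),
                                           heads), heads))
  surfaces <- c(stems, multi)
  type1 <- sample(types, config$lexicon_size, TRUE)
  ambiguous <- runif(config$lexicon_size) < config$ambiguity_rate
  type2 <- rep(NA_character_, config$lexicon_size)
  if (config$n_types > 1L) {
    for (i in which(ambiguous))
      type2[i] <- sample(setdiff(types, type1[i]), 1L)
  }
  cues <- split(cue_words, rep(types, each = 3L))[types]
  # background: canonical case and POS; top ranks act as function words
  canon <- bg
  role <- runif(length(bg))
  canon[role < 0.05] <- toupper(canon[role < 0.05])
  cap <- role >= 0.05 & role < 0.08
  canon[cap] <- sub("^(.)", "\\U\\1", canon[cap], perl = TRUE)
  pos <- sample(c("NN", "VBZ", "JJ", "RB", "VBD", "IN"),
                length(bg), TRUE,
                prob = c(0.35, 0.18, 0.2, 0.09, 0.1, 0.08))
  pos[seq_len(10L)] <- c("DT", "IN", "IN", "CC", "DT", "IN", "TO", "IN",
                         "CC", "DT")
  structure(list(
    surfaces = data.frame(surface = surfaces, type1 = type1, type2 = type2,
                          stringsAsFactors = FALSE),
    cues = cues,
    background = data.frame(word = bg, canonical = canon, pos = pos,
                            stringsAsFactors = FALSE),
    types = types, config = config), class = "synth_lexicon")
}

#' @export
print.synth_lexicon <- function(x, ...) {
  cat(sprintf(
    "<synth_lexicon: %d surfaces (%d ambiguous), %d types, %d filler words>\n",
    nrow(x$surfaces), sum(!is.na(x$surfaces$type2)), length(x$types),
    nrow(x$background)))
  invisible(x)
}

#' Convert the generating lexicon to a tagging lexicon
#'
#' @param slex A `"synth_lexicon"`.
#' @param coverage Fraction of surfaces to keep (1 = full generating
#'   lexicon); sampling is deterministic given `seed`.
#' @param seed Seed for the coverage subsample.
#' @return An `"anatag_lexicon"` mapping each kept surface to its full
#'   type set.
#' @export
as_anatag_lexicon <- function(slex, coverage = 1, seed = 0L) {
  s <- slex$surfaces
  if (coverage < 1) {
    set.seed(seed)
    keep <- sample(nrow(s), round(coverage * nrow(s)))
    s <- s[sort(keep), , drop = FALSE]
  }
  cats <- lapply(seq_len(nrow(s)), function(i)
    c(s$type1[i], if (!is.na(s$type2[i])) s$type2[i]))
  lexicon(s$surface, cats, source = "manual")
}

#' Generate a synthetic annotated corpus
#'
#' Documents consist of a header line (a blank line separates it from the
#' body) and body sentences of Zipf-distributed filler tokens.  Mentions
#' are planted at the configured density, drawn from a small per-document
#' surface pool; an ambiguous surface keeps a single type within a
#' document, and with probability `context_cue_strength` a type-specific
#' cue word is placed directly before a mention (guaranteed at least once
#' per document and ambiguous surface).  Gold standoff, sentence spans,
#' and gold POS/lemma/chunk columns are produced, so feature tests can run
#' in external-annotator mode.
#'
#' @param config A [synth_config()].
#' @param slex A `"synth_lexicon"` (default: generated from `config`).
#' @return An object of class `"synth_corpus"`: `documents` (list of
#'   `"anatag_document"` with gold token columns), `slex`, `gen_lexicon`
#'   (full typed lexicon), `feature_lexicon` (coverage-limited lexicon for
#'   dictionary features), and `config`.
#' @export
generate_corpus <- function(config, slex = generate_lexicon(config)) {
  set.seed(config$seed + 1L)
  bg <- slex$background
  V <- nrow(bg)
  zipf <- (1 / seq_len(V)^1.05); zipf <- zipf / sum(zipf)
  draw_bg <- function(n) sample.int(V, n, TRUE, prob = zipf)
  docs <- vector("list", config$n_docs)
  for (d in seq_len(config$n_docs)) {
    pool <- slex$surfaces[sample(nrow(slex$surfaces),
                                 min(config$surfaces_per_doc,
                                     nrow(slex$surfaces))), , drop = FALSE]
    # one sense per discourse: fix each pooled surface's type for this doc
    doc_type <- ifelse(!is.na(pool$type2) & runif(nrow(pool)) < 0.5,
                       pool$type2, pool$type1)
    n_body <- max(80L, round(rnorm(1, config$doc_length_mean,
                                   config$doc_length_sd)))
    sent_len <- integer(0)
    while (sum(sent_len) < n_body)
      sent_len <- c(sent_len, sample(8:20, 1L))
    n_sent <- length(sent_len)
    # mention count targets the configured density over the FINAL token
    # count (filler + sentence periods + mention and cue tokens)
    rho <- config$mention_density / 1000
    ment_len <- (1 - config$multiword_fraction) +
      config$multiword_fraction * 2.3 + config$context_cue_strength
    n_ment <- rbinom(1L, round((n_body + n_sent) / (1 - rho * ment_len)),
                     rho)
    # header: filler words of length > 3 (title-case detectable)
    long_bg <- which(nchar(bg$word) > 4L & bg$pos %in% c("NN", "JJ", "VBZ"))
    header_idx <- sample(long_bg, sample(5:8, 1L))
    sents <- vector("list", n_sent + 1L)
    sents[[1L]] <- data.frame(surface = bg$canonical[header_idx],
                              lemma = bg$word[header_idx],
                              pos = bg$pos[header_idx],
                              mention = NA_integer_,
                              type = NA_character_,
                              stringsAsFactors = FALSE)
    ment_sent <- if (n_ment) sample(n_sent, n_ment, TRUE) else integer(0)
    mention_counter <- 0L
    cued <- character(0)       # surfaces cued at least once in this doc
    seen_first <- list()       # surface -> c(sent, mention_id) first occ.
    for (s in seq_len(n_sent)) {
      idx <- draw_bg(sent_len[s])
      filler <- data.frame(surface = bg$canonical[idx],
                           lemma = bg$word[idx],
                           pos = bg$pos[idx], mention = NA_integer_,
                           type = NA_character_, stringsAsFactors = FALSE)
      k <- sum(ment_sent == s)
      blocks <- vector("list", k)
      gaps <- if (k) sort(sample(0:sent_len[s], k, TRUE)) else integer(0)
      for (m in seq_len(k)) {
        mention_counter <- mention_counter + 1L
        pi <- sample(nrow(pool), 1L)
        surf <- pool$surface[pi]; mtype <- doc_type[pi]
        words <- strsplit(surf, " ", fixed = TRUE)[[1]]
        mt <- data.frame(surface = words, lemma = words,
                         pos = rep("NN", length(words)),
                         mention = mention_counter, type = mtype,
                         stringsAsFactors = FALSE)
        use_cue <- runif(1) < config$context_cue_strength
        if (!use_cue && !is.na(pool$type2[pi]) && !(surf %in% cued) &&
            is.null(seen_first[[surf]]))
          use_cue <- TRUE   # guarantee one cued occurrence per doc+surface
        if (use_cue) {
          cw <- sample(slex$cues[[mtype]], 1L)
          mt <- rbind(data.frame(surface = cw, lemma = cw, pos = "NN",
                                 mention = NA_integer_,
                                 type = NA_character_,
                                 stringsAsFactors = FALSE), mt)
          cued <- union(cued, surf)
        }
        if (is.null(seen_first[[surf]])) seen_first[[surf]] <- s
        blocks[[m]] <- mt
      }
      # assemble: mention blocks dropped into their filler gaps, so blocks
      # stay contiguous and a cue always directly precedes its mention
      pieces <- list(); prev <- 0L
      for (m in seq_len(k)) {
        if (gaps[m] > prev)
          pieces <- c(pieces, list(filler[(prev + 1L):gaps[m], ,
                                          drop = FALSE]))
        pieces <- c(pieces, list(blocks[[m]]))
        prev <- gaps[m]
      }
      if (prev < sent_len[s])
        pieces <- c(pieces, list(filler[(prev + 1L):sent_len[s], ,
                                        drop = FALSE]))
      pieces <- c(pieces, list(data.frame(surface = ".", lemma = ".",
                                          pos = ".", mention = NA_integer_,
                                          type = NA_character_,
                                          stringsAsFactors = FALSE)))
      sents[[s + 1L]] <- do.call(rbind, pieces)
    }
    docs[[d]] <- realize_synth_document(sprintf("doc%03d", d), sents)
  }
  feature_lexicon <- as_anatag_lexicon(slex, config$dict_coverage,
                                       seed = config$seed + 7L)
  structure(list(documents = docs, slex = slex,
                 gen_lexicon = as_anatag_lexicon(slex),
                 feature_lexicon = feature_lexicon,
                 config = config, case_record = NULL),
            class = "synth_corpus")
}

# lay out sentences as text (header, blank line, body joined by spaces),
# compute offsets, and assemble the document with gold columns
realize_synth_document <- function(doc_id, sents) {
  pieces <- character(0)
  pos <- 0L
  all_tok <- list()
  sent_spans <- data.frame(start = integer(), end = integer())
  for (s in seq_along(sents)) {
    tok <- sents[[s]]
    n <- nrow(tok)
    widths <- nchar(tok$surface)
    starts <- pos + cumsum(c(0L, widths[-n] + 1L))
    ends <- starts + widths
    tok$start <- starts; tok$end <- ends
    tok$sentence <- s
    sent_spans <- rbind(sent_spans,
                        data.frame(start = starts[1], end = ends[n]))
    pieces <- c(pieces, paste(tok$surface, collapse = " "))
    sep <- if (s == 1L) "\n\n" else " "
    pos <- ends[n] + nchar(sep)
    all_tok[[s]] <- tok
  }
  text <- paste0(pieces[1], "\n\n",
                 paste(pieces[-1], collapse = " "))
  tok <- do.call(rbind, all_tok)
  # chunk layer from POS, per sentence
  np <- tok$pos %in% c("DT", "JJ", "CD") | startsWith(tok$pos, "NN")
  newgrp <- np & (!c(FALSE, np[-length(np)]) |
                    c(TRUE, diff(tok$sentence) != 0L))
  tok$chunk <- ifelse(np, ifelse(newgrp, "B-NP", "I-NP"), "O")
  ment <- tok$mention
  mrows <- which(!is.na(ment))
  if (length(mrows)) {
    ids <- unique(ment[mrows])
    ms <- vapply(ids, function(i) min(tok$start[which(ment == i)]),
                 integer(1))
    me <- vapply(ids, function(i) max(tok$end[which(ment == i)]),
                 integer(1))
    mt <- vapply(ids, function(i) tok$type[which(ment == i)[1]],
                 character(1))
    mtab <- mentions(ms, me, mt, doc_text = text)
  } else mtab <- mentions()
  tok$mention <- NULL; tok$type <- NULL
  rownames(tok) <- NULL
  document(text, doc_id, mentions = mtab, sentences = sent_spans,
           tokens = tok[, c("surface", "start", "end", "sentence",
                            "lemma", "pos", "chunk")])
}

#' Apply case distortion to a synthetic corpus
#'
#' Emulates the orthographic conventions truecasing undoes: capitalizes
#' sentence-initial tokens, and renders header lines in Title Case or
#' ALL-UPPER at the configured rates.  Token offsets are unchanged (case
#' never changes string length); the mapping from distorted back to
#' original surfaces is retained in `case_record` for scoring restoration.
#'
#' @param corpus A `"synth_corpus"`.
#' @param config Defaults to the corpus's own config.
#' @return The corpus with distorted documents and a `case_record`
#'   data.frame (`doc_id`, `token`, `original`, `distorted`).
#' @export
distort_case <- function(corpus, config = corpus$config) {
  set.seed(config$seed + 2L)
  recs <- list()
  for (d in seq_along(corpus$documents)) {
    doc <- corpus$documents[[d]]
    tok <- doc$tokens
    orig <- tok$surface
    new <- orig
    r <- runif(1)
    hdr <- which(tok$sentence == 1L)
    if (r < config$case_title_rate) {
      new[hdr] <- sub("^(\\p{Ll})", "\\U\\1", new[hdr], perl = TRUE)
    } else if (r < config$case_title_rate + config$case_allcaps_rate) {
      new[hdr] <- toupper(new[hdr])
    }
    first_of_sent <- which(!duplicated(tok$sentence) & tok$sentence > 1L)
    do_cap <- first_of_sent[runif(length(first_of_sent)) <
                              config$case_sentence_initial]
    new[do_cap] <- sub("^(\\p{Ll})", "\\U\\1", new[do_cap], perl = TRUE)
    changed <- which(new != orig)
    if (length(changed)) {
      text <- doc$text
      for (i in changed)
        substr(text, tok$start[i] + 1L, tok$end[i]) <- new[i]
      tok$surface <- new
      doc$text <- text
      doc$tokens <- tok
      if (nrow(doc$mentions))
        doc$mentions$text <- substr0(text, doc$mentions$start,
                                     doc$mentions$end)
      corpus$documents[[d]] <- doc
      recs[[length(recs) + 1L]] <-
        data.frame(doc_id = doc$doc_id, token = changed,
                   original = orig[changed], distorted = new[changed],
                   stringsAsFactors = FALSE)
    }
  }
  corpus$case_record <- if (length(recs)) do.call(rbind, recs) else
    data.frame(doc_id = character(), token = integer(),
               original = character(), distorted = character())
  corpus
}

#' @export
print.synth_corpus <- function(x, ...) {
  nm <- sum(vapply(x$documents, function(d) nrow(d$mentions), integer(1)))
  nt <- sum(vapply(x$documents, function(d) nrow(d$tokens), integer(1)))
  cat(sprintf("<synth_corpus: %d docs, %d tokens, %d mentions (%.1f/1000)%s>\n",
              length(x$documents), nt, nm, 1000 * nm / nt,
              if (!is.null(x$case_record)) ", case-distorted" else ""))
  invisible(x)
}
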