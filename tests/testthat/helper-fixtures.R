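# shared fixtures, all built in code

# a tiny standoff-annotated document
tiny_doc <- function() {
  txt <- "Mast cells migrate. The heart pumps blood."
  ann <- paste0("T1\tCell 0 10\tMast cells\n",
                "T2\tOrgan 24 29\theart\n",
                "T3\tOrganism_substance 36 41\tblood\n")
  read_standoff(txt, ann, doc_id = "tiny")
}

# random mention set aligned to token boundaries of a synthetic text
random_mention_doc <- function(n_tokens = 30, p_mention = 0.2,
                               types = c("Cell", "Organ", "Tissue")) {
  words <- replicate(n_tokens, paste(sample(letters, sample(3:7, 1),
                                            replace = TRUE), collapse = ""))
  text <- paste(words, collapse = " ")
  tok <- tokenize(text)
  n <- nrow(tok)
  starts <- integer(); ends <- integer(); ty <- character()
  i <- 1L
  while (i <= n) {
    if (runif(1) < p_mention) {
      len <- min(sample(1:3, 1), n - i + 1L)
      starts <- c(starts, tok$start[i]); ends <- c(ends, tok$end[i + len - 1L])
      ty <- c(ty, sample(types, 1))
      i <- i + len
    } else i <- i + 1L
  }
  document(text, doc_id = "rand",
           mentions = mentions(starts, ends, ty, doc_text = text),
           tokens = tok)
}

# brute-force tokenizer: character-class scan, the independent oracle
oracle_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  cls <- ifelse(grepl("^[\\p{L}\\p{N}]$", chars, perl = TRUE), "an",
                ifelse(grepl("^\\s$", chars), "ws", "sym"))
  out <- data.frame(surface = character(), start = integer(),
                    end = integer())
  i <- 1L
  while (i <= length(chars)) {
    if (cls[i] == "ws") { i <- i + 1L; next }
    if (cls[i] == "sym") {
      out <- rbind(out, data.frame(surface = chars[i], start = i - 1L,
                                   end = i))
      i <- i + 1L
    } else {
      j <- i
      while (j < length(chars) && cls[j + 1L] == "an") j <- j + 1L
      out <- rbind(out, data.frame(
        surface = paste(chars[i:j], collapse = ""), start = i - 1L,
        end = j))
      i <- j + 1L
    }
  }
  out
}

# a small deterministic synthetic corpus for pipeline-level tests
small_corpus <- function(seed = 5, n_docs = 6, len = 250, lex = 50) {
  cfg <- synth_config(seed = seed, n_docs = n_docs, doc_length_mean = len,
                      doc_length_sd = 40, lexicon_size = lex,
                      background_vocab = 400)
  generate_corpus(cfg)
}

# hand-built CRF model with fixed weights, for decoding tests
toy_crf <- function(features, labels, seed = 1) {
  set.seed(seed)
  F_ <- length(features); L_ <- length(labels)
  structure(list(weights = round(rnorm(F_ * L_ + L_ * L_, 0, 1), 3),
                 features = features, labels = labels, l2 = 1),
            class = "anatag_crf")
}

# exhaustive Viterbi oracle: enumerate all label sequences
oracle_decode <- function(model, seq_feats, bias_vec) {
  co <- coef(model)
  L <- length(model$labels)
  n <- length(seq_feats)
  E <- t(vapply(seq_feats, function(f) {
    idx <- match(f, model$features); idx <- idx[!is.na(idx)]
    if (length(idx)) rowSums(co$state[, idx, drop = FALSE]) + bias_vec
    else bias_vec
  }, numeric(L)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  sc <- apply(grid, 1L, function(g) {
    s <- sum(E[cbind(seq_len(n), g)])
    if (n > 1L) s <- s + sum(co$trans[cbind(g[-n], g[-1L])])
    s
  })
  model$labels[grid[which.max(sc), ]]
}
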