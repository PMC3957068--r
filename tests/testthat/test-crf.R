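simple_tokens <- function(words) {
  text <- paste(words, collapse = " ")
  tokenize(text)
}

test_that("BIO encoding marks mention starts, insides and outsides", {
  tok <- simple_tokens(c("mast", "cells", "migrate"))
  m <- mentions(0L, 10L, "Cell", doc_text = "mast cells migrate")
  expect_equal(encode_bio(tok, m), c("B-Cell", "I-Cell", "O"))
  expect_equal(encode_bio(tok, mentions()), c("O", "O", "O"))
  # adjacent same-type mentions stay distinct: B then B, never B I
  tok2 <- simple_tokens(c("liver", "heart"))
  m2 <- mentions(c(0L, 6L), c(5L, 11L), c("Organ", "Organ"),
                 doc_text = "liver heart")
  expect_equal(encode_bio(tok2, m2), c("B-Organ", "B-Organ"))
})

test_that("misaligned mention boundaries snap outward or error", {
  tok <- simple_tokens(c("platelet", "derived"))
  m <- data.frame(start = 0L, end = 4L, type = "Cell", text = NA)
  expect_warning(lab <- encode_bio(tok, m), "snapped")
  expect_equal(lab, c("B-Cell", "O"))
  expect_error(encode_bio(tok, m, boundary = "error"), "not aligned")
})

test_that("BIO decoding inverts encoding and repairs invalid sequences", {
  tok <- simple_tokens(c("mast", "cells", "migrate"))
  m <- decode_bio(c("B-Cell", "I-Cell", "O"), tok)
  expect_equal(m$start, 0L); expect_equal(m$end, 10L)
  expect_equal(m$type, "Cell")
  # orphan I after O is repaired to a mention start
  r <- decode_bio(c("O", "I-Organ", "O"), tok)
  expect_equal(nrow(r), 1L)
  expect_equal(r$type, "Organ")
  expect_equal(r$start, tok$start[2])
  # type switch inside a run starts a new mention
  r2 <- decode_bio(c("B-Cell", "I-Organ", "I-Organ"), tok)
  expect_equal(r2$type, c("Cell", "Organ"))
})

test_that("encode/decode round-trips over random mention sets", {
  set.seed(55)
  for (rep in 1:25) {
    d <- random_mention_doc()
    lab <- encode_bio(d$tokens, d$mentions)
    back <- decode_bio(lab, d$tokens)
    expect_equal(back[, c("start", "end", "type")],
                 d$mentions[, c("start", "end", "type")])
  }
})

make_toy_training <- function() {
  # feature "is_cell" fires only with B-Cell; "ctx" is uninformative
  x <- list(list(c("is_cell", "ctx"), "ctx"),
            list("ctx", c("is_cell", "ctx")),
            list("ctx", "ctx"),
            list(c("is_cell", "ctx")))
  y <- list(c("B-Cell", "O"), c("O", "B-Cell"), c("O", "O"),
            "B-Cell")
  list(x = x, y = y, labels = c("O", "B-Cell", "I-Cell"))
}

test_that("training learns perfectly predictive features", {
  tr <- make_toy_training()
  m <- crf(tr$x, tr$y, tr$labels, l2 = 0.1, max_iter = 200)
  pred <- predict(m, list(list(c("is_cell", "ctx"), "ctx")))
  expect_equal(pred[[1]], c("B-Cell", "O"))
  # weights associate the diagnostic feature with its label
  co <- coef(m)
  expect_gt(co$state["B-Cell", "is_cell"], co$state["O", "is_cell"])
})

test_that("training rejects invalid inputs before starting", {
  tr <- make_toy_training()
  expect_error(crf(list(), list(), tr$labels), "empty")
  bad_y <- tr$y; bad_y[[1]][1] <- "B-Nope"
  expect_error(crf(tr$x, bad_y, tr$labels), "outside the label set")
  expect_error(crf(tr$x, tr$y, tr$labels, l2 = 0), "positive")
})

test_that("stronger regularization never improves training likelihood", {
  tr <- make_toy_training()
  nlls <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6), function(l2v) {
    m <- crf(tr$x, tr$y, tr$labels, l2 = l2v, max_iter = 300)
    crf_neg_loglik(m, tr$x, tr$y, penalized = FALSE)
  }, numeric(1))
  expect_true(all(diff(nlls) > -1e-6))
})

test_that("training is deterministic", {
  tr <- make_toy_training()
  m1 <- crf(tr$x, tr$y, tr$labels, l2 = 0.3)
  m2 <- crf(tr$x, tr$y, tr$labels, l2 = 0.3)
  expect_identical(m1$weights, m2$weights)
  test_x <- list(list("ctx", c("is_cell", "ctx"), "ctx"))
  expect_identical(predict(m1, test_x), predict(m2, test_x))
})

test_that("Viterbi equals exhaustive enumeration on small problems", {
  set.seed(77)
  labels <- c("O", "B-Cell", "I-Cell", "B-Organ", "I-Organ")
  featpool <- paste0("f", 1:10)
  model <- toy_crf(featpool, labels)
  co <- coef(model)
  score_of <- function(seq_feats, path, bias_vec) {
    idxs <- lapply(seq_feats, function(f) {
      ii <- match(f, model$features); ii[!is.na(ii)]
    })
    li <- match(path, labels)
    s <- sum(vapply(seq_along(path), function(t)
      sum(co$state[li[t], idxs[[t]]]) + bias_vec[li[t]], numeric(1)))
    n <- length(path)
    if (n > 1) s <- s + sum(co$trans[cbind(li[-n], li[-1])])
    s
  }
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    seq_feats <- lapply(seq_len(n), function(i)
      sample(featpool, sample(1:3, 1)))
    for (dc in list(decode_config(),
                    decode_config(O = -0.4, B = 0.3, I = 0.1))) {
      bias_vec <- anatag:::expand_bias(dc, labels)
      got <- predict(model, list(seq_feats), bias = dc)[[1]]
      oracle <- oracle_decode(model, seq_feats, bias_vec)
      expect_equal(score_of(seq_feats, got, bias_vec),
                   score_of(seq_feats, oracle, bias_vec),
                   tolerance = 1e-9)
    }
  }
})

test_that("label bias: zero is the identity, dominance forces B labels", {
  tr <- make_toy_training()
  m <- crf(tr$x, tr$y, tr$labels, l2 = 0.1)
  x <- list(list("ctx", c("is_cell", "ctx")), list("ctx"))
  expect_identical(predict(m, x),
                   predict(m, x, bias = decode_config(0, 0, 0)))
  huge <- predict(m, x, bias = decode_config(B = 1e6))
  expect_true(all(startsWith(unlist(huge), "B-")))
})

test_that("per-label bias overrides the class-level weight", {
  labels <- c("O", "B-Cell", "I-Cell")
  model <- toy_crf(c("f1", "f2"), labels)
  x <- list(list("f1", "f2", "f1"))
  strong <- decode_config(per_label = c("B-Cell" = 1e6))
  out <- predict(model, x, bias = strong)[[1]]
  expect_true(all(out == "B-Cell"))
  expect_error(predict(model, x,
                       bias = decode_config(per_label = c(Bogus = 1))),
               "outside the label set")
})

test_that("unseen features at decode time contribute nothing", {
  tr <- make_toy_training()
  m <- crf(tr$x, tr$y, tr$labels, l2 = 0.1)
  with_unseen <- predict(m, list(list(c("is_cell", "never_seen"))))
  without <- predict(m, list(list("is_cell")))
  expect_identical(with_unseen, without)
})
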