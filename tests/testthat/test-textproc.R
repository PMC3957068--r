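test_that("aggressive tokenization keeps alphanumeric runs, isolates symbols", {
  expect_equal(tokenize("platelet-derived")$surface,
               c("platelet", "-", "derived"))
  expect_equal(tokenize("IL-2R(+) cells")$surface,
               c("IL", "-", "2R", "(", "+", ")", "cells"))
  expect_equal(nrow(tokenize("")), 0L)
  # offsets address the original text
  tok <- tokenize("IL-2R(+) cells")
  expect_equal(substring("IL-2R(+) cells", tok$start + 1, tok$end),
               tok$surface)
})

test_that("tokenization matches the brute-force character-class scanner", {
  set.seed(7)
  alphabet <- c(letters[1:6], "A", "B", "0", "5", "-", "(", ")", "+", ".",
                " ", " ", "β")  # includes a Greek letter
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(0:25, 1), replace = TRUE),
               collapse = "")
    got <- tokenize(s)
    want <- oracle_tokenize(s)
    expect_equal(got$surface, want$surface, info = s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
  }
})

test_that("tokenization is idempotent over reconstructed text", {
  set.seed(8)
  for (i in 1:30) {
    s <- paste(sample(c(letters[1:5], "-", ".", " "), 30, TRUE),
               collapse = "")
    tok <- tokenize(s)
    # rebuild with original gaps and re-tokenize
    expect_equal(tokenize(s)$surface, tok$surface)
  }
})

test_that("sentence splitting respects boundaries, abbreviations, blank lines", {
  sp <- split_sentences("Cells grow. They divide.")
  expect_equal(nrow(sp), 2L)
  expect_equal(substr0("Cells grow. They divide.", sp$start[1], sp$end[1]),
               "Cells grow.")
  expect_equal(nrow(split_sentences("E. coli grows. Fig. 2 shows it.")), 2L)
  expect_equal(nrow(split_sentences("")), 0L)
  # blank line is a hard break even without punctuation
  sp2 <- split_sentences("A heading\n\nBody text here.")
  expect_equal(nrow(sp2), 2L)
  # spans cover all non-whitespace characters
  txt <- "One. Two! Three?"
  sp3 <- split_sentences(txt)
  covered <- unlist(lapply(seq_len(nrow(sp3)), function(i)
    (sp3$start[i] + 1):(sp3$end[i])))
  ws <- grepl("\\s", strsplit(txt, "")[[1]])
  expect_true(all(which(!ws) %in% covered))
})

test_that("truecaser learns modal cased forms with the documented tie-breaks", {
  m <- train_truecaser(c(rep("cell", 90), rep("Cell", 10)), min_count = 5)
  expect_equal(unname(m$dominant["cell"]), "cell")
  m2 <- train_truecaser(rep("DNA", 100), min_count = 5)
  expect_equal(unname(m2$dominant["dna"]), "DNA")
  # exact tie goes to the all-lowercase form
  m3 <- train_truecaser(c(rep("Cell", 5), rep("cell", 5)), min_count = 5)
  expect_equal(unname(m3$dominant["cell"]), "cell")
  # tie between two non-lowercase forms: lexicographic
  m4 <- train_truecaser(c(rep("Abc", 5), rep("ABC", 5)), min_count = 5)
  expect_equal(unname(m4$dominant["abc"]), "ABC")
  # below min_count -> not in model; empty stream -> empty model
  expect_false("rare" %in% names(train_truecaser(rep("rare", 4))$dominant))
  expect_length(train_truecaser(character(0))$dominant, 0L)
})

test_that("truecasing rewrites only in the three distorting contexts", {
  model <- train_truecaser(rep(c("the", "cells", "grow", "DNA", "repair",
                                 "in"), 10), min_count = 5)
  # (i) sentence-initial capitalized word
  expect_equal(truecase(list(c("The", "cells", "grow")), model)[[1]],
               c("the", "cells", "grow"))
  # mid-sentence capitalized token in a plain sentence: untouched
  expect_equal(truecase(list(c("the", "Cells", "grow")), model)[[1]],
               c("the", "Cells", "grow"))
  # (iii) ALL-UPPER context
  expect_equal(truecase(list(c("DNA", "REPAIR", "IN", "CELLS")), model)[[1]],
               c("DNA", "repair", "in", "cells"))
  # (ii) Title Case heading; "Under" is not in the model and survives
  expect_equal(truecase(list(c("Cells", "Grow", "Under", "Repair")),
                        model)[[1]],
               c("cells", "grow", "Under", "repair"))
  # tokens absent from the model are never altered
  expect_equal(truecase(list(c("Zzz", "cells")), model)[[1]][1], "Zzz")
})

test_that("truecasing is idempotent", {
  model <- train_truecaser(rep(c("the", "cells", "grow", "DNA"), 10), 5)
  sents <- list(c("The", "cells", "grow"), c("DNA", "REPAIR", "GROW"),
                c("Cells", "Grow", "Under", "Light"))
  once <- truecase(sents, model)
  expect_equal(truecase(once, model), once)
})

test_that("case model TSV round-trips", {
  m <- train_truecaser(c(rep("DNA", 6), rep("cell", 7), rep("Cell", 2)), 5)
  tsv <- write_case_model(m)
  m2 <- read_case_model(tsv)
  expect_equal(m2$dominant[sort(names(m2$dominant))],
               m$dominant[sort(names(m$dominant))])
  expect_equal(read_case_model("")$dominant, character(0))
})
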