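obo_fixture <- "
[Term]
id: X:0
name: organ

[Term]
id: X:1
name: heart
is_a: X:0 ! organ
synonym: \"cardiac muscle\" EXACT []

[Term]
id: X:2
name: old heart
is_a: X:1
is_obsolete: true
"

test_that("OBO stanzas parse: ids, names, synonyms, is_a, obsolete", {
  g <- parse_obo(obo_fixture)
  expect_equal(sort(names(g$terms)), c("X:0", "X:1", "X:2"))
  expect_equal(g$terms[["X:1"]]$name, "heart")
  expect_equal(g$terms[["X:1"]]$is_a, "X:0")
  expect_equal(g$terms[["X:1"]]$synonyms, "cardiac muscle")
  expect_true(g$terms[["X:2"]]$obsolete)
  expect_equal(g$roots, "X:0")
  expect_error(parse_obo("[Term]\nname: orphan\n"), "without id")
  cyc <- "[Term]\nid: A\nis_a: B\n\n[Term]\nid: B\nis_a: A\n"
  expect_error(parse_obo(cyc), "cycle")
})

test_that("OBO lexicon compilation follows is-a ascent and caps categories", {
  g <- parse_obo(obo_fixture)
  lex <- compile_obo_lexicon(g, c("X:0" = "Organ"), expand = FALSE)
  expect_setequal(lex$categories[[match("heart", lex$keys)]], "Organ")
  expect_setequal(lex$categories[[match("cardiac muscle", lex$keys)]],
                  "Organ")
  # obsolete terms contribute nothing
  expect_false("old heart" %in% lex$keys)
  # a term reaching no mapped ancestor gets "other"
  expect_setequal(lex$categories[[match("organ", lex$keys)]], "Organ")
  lex2 <- compile_obo_lexicon(g, setNames(character(0), character(0)),
                              expand = FALSE)
  expect_setequal(unlist(lex2$categories), "other")

  # two parents mapping to different categories -> union
  g2 <- parse_obo(paste0("[Term]\nid: U:1\nname: up1\n\n",
                         "[Term]\nid: U:2\nname: up2\n\n",
                         "[Term]\nid: U:3\nname: leaf\nis_a: U:1\nis_a: U:2\n"))
  lex3 <- compile_obo_lexicon(g2, c("U:1" = "Organ", "U:2" = "Tissue"),
                              expand = FALSE)
  expect_setequal(lex3$categories[[match("leaf", lex3$keys)]],
                  c("Organ", "Tissue"))

  # top_k capping relabels infrequent categories to "other"
  stanzas <- paste0(vapply(1:5, function(i) sprintf(
    "[Term]\nid: A:%d\nname: worda%d\nis_a: TOPA\n\n", i, i), ""),
    collapse = "")
  stanzas <- paste0(stanzas, "[Term]\nid: B:1\nname: wordb\nis_a: TOPB\n\n",
                    "[Term]\nid: TOPA\nname: topa\n\n",
                    "[Term]\nid: TOPB\nname: topb\n")
  g3 <- parse_obo(stanzas)
  lex4 <- compile_obo_lexicon(g3, c(TOPA = "A", TOPB = "B"), top_k = 1L,
                              expand = FALSE)
  expect_setequal(lex4$categories[[match("wordb", lex4$keys)]], "other")
  expect_setequal(lex4$categories[[match("worda1", lex4$keys)]], "A")
})

test_that("OBO category assignment equals brute-force transitive closure", {
  set.seed(31)
  for (rep in 1:15) {
    n <- 50L
    ids <- paste0("T:", seq_len(n))
    # random DAG: edges only from higher to lower index
    parents <- lapply(seq_len(n), function(i)
      if (i == 1L) character(0) else
        ids[sample(seq_len(i - 1L), min(sample(0:2, 1), i - 1L))])
    content <- paste0(vapply(seq_len(n), function(i) paste0(
      "[Term]\nid: ", ids[i], "\nname: w", i, "\n",
      paste0("is_a: ", parents[[i]], "\n", collapse = ""), "\n"),
      ""), collapse = "")
    g <- parse_obo(content)
    upper_ids <- sample(ids, 5L)
    upper_map <- setNames(paste0("C", seq_along(upper_ids)), upper_ids)
    lex <- compile_obo_lexicon(g, upper_map, expand = FALSE)
    # oracle: reflexive-transitive closure by repeated squaring of the
    # reachability matrix
    adj <- diag(n) > 0
    for (i in seq_len(n)) for (p in parents[[i]])
      adj[i, match(p, ids)] <- TRUE
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
    for (i in seq_len(n)) {
      want <- sort(unique(unname(upper_map[intersect(ids[reach[i, ]],
                                                     names(upper_map))])))
      if (!length(want)) want <- "other"
      got <- sort(lex$categories[[match(paste0("w", i), lex$keys)]])
      expect_equal(got, want)
    }
  }
})

test_that("variant expansion adds plurals, case and hyphen alternates", {
  expect_true("arteries" %in% expand_variants("artery"))
  v <- expand_variants("epithelial cell")
  expect_true(all(c("epithelial cells", "epithelial-cell") %in% v))
  expect_true("blood" %in% expand_variants("blood"))
  expect_true("branch" %in% expand_variants("branches"))
  expect_error(expand_variants(""), "empty")
})

test_that("majority filter keeps types seen in at least half the occurrences", {
  rec <- data.frame(
    string = c(rep("cell", 10), rep("serum", 4), rep("x", 3)),
    types = c(rep("Cell", 7), rep("Cell,Tissue", 3),
              c("Substance", "Substance", "Organ", "Tissue"),
              c("A", "B", "C")),
    stringsAsFactors = FALSE)
  lex <- compile_majority_lexicon(rec)
  # cell: Cell 10/10, Tissue 3/10 -> {Cell}
  expect_setequal(lex$categories[[match("cell", lex$keys)]], "Cell")
  # serum: Substance 2/4 = exactly half -> kept (boundary inclusive)
  expect_setequal(lex$categories[[match("serum", lex$keys)]], "Substance")
  # x: every type below 1/2 -> excluded entirely
  expect_false("x" %in% lex$keys)
  expect_length(compile_majority_lexicon(rec[0, ]), 0L)
})

test_that("majority filter equals a counting oracle on random tables", {
  set.seed(17)
  types <- LETTERS[1:5]
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    rec <- data.frame(
      string = sample(c("s1", "s2", "s3"), n, TRUE),
      stringsAsFactors = FALSE)
    rec$types <- vapply(seq_len(n), function(i)
      paste(sample(types, sample(1:3, 1)), collapse = ","), "")
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    lex <- compile_majority_lexicon(rec, threshold = thr)
    for (s in unique(rec$string)) {
      occ <- strsplit(rec$types[rec$string == s], ",")
      cnt <- table(unlist(lapply(occ, unique)))
      want <- sort(names(cnt)[as.integer(cnt) >= thr * length(occ)])
      got <- if (s %in% lex$keys)
        sort(lex$categories[[match(s, lex$keys)]]) else character(0)
      expect_equal(got, want)
    }
  }
})

test_that("dictionary tagging modes behave as specified", {
  lex <- lexicon(c("growth of cells", "cells", "red blood cell"),
                 list("other", "Cell", "Cell"))
  tok <- tokenize("growth of cells")
  tok$pos <- c("NN", "IN", "NNS")
  all_m <- tag_dictionary(tok, lex, mode = "all")
  # both the long span and the embedded single token
  expect_equal(nrow(all_m), 2L)
  expect_true(any(all_m$start == 1 & all_m$end == 4))
  expect_true(any(all_m$start == 3 & all_m$end == 4))
  lng <- tag_dictionary(tok, lex, mode = "longest")
  expect_equal(nrow(lng), 1L)
  expect_equal(c(lng$start, lng$end), c(1L, 4L))
  tokm <- tag_dictionary(tok, lex, mode = "token")
  expect_equal(nrow(tokm), 1L)
  expect_equal(c(tokm$start, tokm$end), c(3L, 4L))

  # POS filter requires a noun in the span
  tok2 <- tokenize("red blood cell")
  tok2$pos <- c("JJ", "NN", "NN")
  expect_equal(nrow(tag_dictionary(tok2, lex, "all",
                                   pos_filter = "require_nn")), 1L)
  tok2$pos <- c("JJ", "JJ", "JJ")
  expect_equal(nrow(tag_dictionary(tok2, lex, "all",
                                   pos_filter = "require_nn")), 0L)

  # empty lexicon, parameter validation
  expect_equal(nrow(tag_dictionary(tok, lexicon(), "all")), 0L)
  expect_error(tag_dictionary(tok, lex, max_span = 0L), "max_span")
})

test_that("hyphen and space alternate in dictionary matching", {
  lex <- lexicon("epithelial cell", list("Cell"))
  tok <- tokenize("an epithelial-cell layer")
  m <- tag_dictionary(tok, lex, mode = "all")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(2L, 5L))  # epithelial - cell
})

test_that("mode=all equals brute-force span enumeration; modes nest", {
  set.seed(23)
  vocab <- c("aa", "bb", "cc", "dd", "ee")
  for (rep in 1:200) {
    n_entries <- sample(1:6, 1)
    surfs <- unique(replicate(n_entries, paste(
      sample(vocab, sample(1:3, 1), TRUE), collapse = " ")))
    lex <- lexicon(surfs, as.list(rep("X", length(surfs))))
    n <- sample(1:12, 1)
    tok <- data.frame(surface = sample(vocab, n, TRUE),
                      sentence = sort(sample(1:2, n, TRUE)),
                      pos = sample(c("NN", "JJ"), n, TRUE))
    max_span <- 4L
    got <- tag_dictionary(tok, lex, mode = "all", max_span = max_span)
    # oracle: enumerate every span up to max_span and test membership
    want <- list()
    for (i in seq_len(n)) for (j in i:min(n, i + max_span - 1L)) {
      if (tok$sentence[i] != tok$sentence[j]) next
      key <- canonical_surface(paste(tok$surface[i:j], collapse = " "))
      if (key %in% lex$keys)
        want[[length(want) + 1L]] <- c(i, j + 1L)
    }
    want <- if (length(want)) do.call(rbind, want) else
      matrix(integer(0), ncol = 2)
    canon <- function(m) matrix(as.integer(m[order(m[, 1], m[, 2]), ]),
                                ncol = 2)
    got_m <- as.matrix(got[, c("start", "end")])
    expect_equal(canon(got_m), canon(want))

    # leftmost-longest equals the greedy oracle over the all-candidates set
    lng <- tag_dictionary(tok, lex, mode = "longest", max_span = max_span)
    w <- want[order(want[, 1], -(want[, 2] - want[, 1])), , drop = FALSE]
    sel <- matrix(integer(0), ncol = 2); pos <- 1L
    for (r in seq_len(nrow(w))) {
      if (w[r, 1] >= pos) { sel <- rbind(sel, w[r, ]); pos <- w[r, 2] }
    }
    expect_equal(matrix(as.integer(as.matrix(lng[, c("start", "end")])),
                        ncol = 2),
                 matrix(as.integer(sel), ncol = 2))
    # longest-mode spans never overlap
    if (nrow(lng) > 1L)
      expect_true(all(lng$start[-1L] >= lng$end[-nrow(lng)]))
    # POS-filtered candidates are a subset of the unfiltered ones
    filt <- tag_dictionary(tok, lex, mode = "all",
                           pos_filter = "require_nn",
                           max_span = max_span)
    expect_true(all(paste(filt$start, filt$end) %in%
                      paste(got$start, got$end)))
  }
})

test_that("dictionary matches become BIO-style token features", {
  m <- data.frame(start = c(1L, 2L), end = c(3L, 4L))
  m$categories <- list("Organ", c("A", "B"))
  f <- matches_to_features(m, 4L)
  expect_equal(f[[1]], "DICT-B-Organ")
  expect_setequal(f[[2]], c("DICT-I-Organ", "DICT-B-A", "DICT-B-B"))
  expect_setequal(f[[3]], c("DICT-I-A", "DICT-I-B"))
  expect_equal(f[[4]], character(0))
  expect_equal(matches_to_features(m[0, ], 2L),
               list(character(0), character(0)))
})

test_that("lexicon TSV round-trips and validates", {
  lex <- lexicon(c("heart", "red blood cell"), list("Organ", "Cell"))
  tsv <- write_lexicon(lex)
  lex2 <- read_lexicon(tsv)
  expect_equal(lex2$keys, lex$keys)
  expect_equal(lex2$categories, lex$categories)
  expect_error(lexicon("x", list(character(0))), "empty category")
  expect_error(lexicon("", list("A")), "empty surface")
})

test_that("occurrence-record TSV feeds the majority filter", {
  tsv <- "cell\tCell\ncell\tCell,Tissue\ncell\tTissue\nserum\tSubstance\n"
  rec <- read_occurrences(tsv)
  expect_equal(nrow(rec), 4L)
  lex <- compile_majority_lexicon(rec)
  expect_setequal(lex$categories[[match("cell", lex$keys)]],
                  c("Cell", "Tissue"))
  expect_error(read_occurrences("a\tb\tc\n"), "2 TSV fields")
})
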