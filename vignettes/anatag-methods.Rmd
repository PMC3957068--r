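---
title: "Recognizing anatomical entity mentions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing anatomical entity mentions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the model

`anatag` recognizes *anatomical entity mentions* — references to organism
parts at levels of organization between macromolecule and whole organism —
in free text, and assigns each mention one of twelve disjoint upper-level
types (`anatag_types()`): organism subdivisions, anatomical systems,
organs, multi-tissue structures, tissues, cells, developing anatomical
structures, cellular components, organism substances, immaterial
anatomical entities, pathological formations, and cancers.

Because mentions are contiguous, non-overlapping character spans with
disjoint types, the task is cast as sequential labeling: each token is
labeled **B**-t (beginning of a mention of type t), **I**-t (inside), or
**O** (outside), giving 25 labels in the multiclass setting and 3 in the
single-class (untyped) setting.  The sequence model is a linear-chain
conditional random field

$$ p(y \mid x) \propto \exp\Big( \sum_t \big(\textstyle\sum_{f \in
x_t} w_{f,y_t}\big) + \sum_t T_{y_{t-1},y_t} \Big), $$

with one weight per (string feature, label) pair and a dense label-label
transition matrix.  Training maximizes the L2-penalized conditional
likelihood (penalty $\tfrac{\lambda}{2}\lVert\theta\rVert^2$) by L-BFGS on
the exact forward-backward gradient; the forward-backward pass uses
per-position scaling, so no likelihood computation happens in the
exponent domain.  Decoding is Viterbi.  Both are implemented in C++
inside the package; training is deterministic given the data and
configuration.

## Label-bias decoding

CRF taggers trained for accuracy favor the majority label **O**, which
yields high-precision, low-recall tagging.  Rather than retraining, the
decoder accepts additive *label-bias* weights per label class
(`decode_config(O=, B=, I=)`, with per-label overrides): each position's
label scores are shifted by the bias before Viterbi.  Raising the B bias
(or lowering O) produces more mentions; zero bias is exactly the standard
decode.  The package exposes a grid search (`anatag(..., devel=,
l2_grid=, bias_grid=)`) that selects the regularization coefficient and
B bias by development-set right-boundary F-score.  The default grids are
$\lambda \in \{0.05, 0.1, 0.5, 1, 2, 5\}$ and B bias $\in \{0, 0.1,
\ldots, 1\}$; both are explicit package defaults, chosen as round
values bracketing the useful range on the synthetic corpora.

# The feature pipeline

Input text is segmented into sentences (a rule-based splitter with an
abbreviation list; pre-segmented CoNLL input bypasses it — segmentation
is deliberately pluggable, since it is not where the method's value
lies), then tokenized *aggressively*: every maximal run of Unicode
letters/digits is a token and every other non-whitespace character is its
own token, so boundaries inside forms like "platelet-derived" are
reachable.  "Alphanumeric" includes all Unicode letters because Greek
letters occur inside biomedical terms.

**Truecasing.**  Orthographic convention distorts case in three contexts:
sentence-initial capitalization, Title Case headings, and ALL-UPPER
blocks.  A unigram case model — the most frequent cased variant of each
word in a background corpus, counted off sentence-initial positions —
rewrites tokens to their dominant form *only* in those contexts.  The
model trusts a key only with ≥ 5 occurrences by default; ties prefer the
all-lowercase form, then lexicographic order, so builds are
deterministic.  Context detectors (no reference definition exists, so
these are package choices): Title Case when ≥ 75% of alphabetic tokens
longer than 3 characters are capitalized and there are at least 3 such
tokens; ALL-UPPER when ≥ 90% of alphabetic characters are uppercase over
at least 2 alphabetic tokens.  Truecasing touches only the
feature-visible surface, never the stored text or offsets, and is
idempotent by construction (every rewrite target is a fixed point of the
model).

**Dictionary features.**  Lexicons map surface strings to category sets
and can be compiled two ways:

* from OBO ontologies (`compile_obo_lexicon`): every non-obsolete term's
  name and synonyms map to the upper-level categories reachable by
  transitive is-a ascent; terms reaching no mapped ancestor get `other`;
  only the 100 most frequent categories are kept (the rest collapse to
  `other`) to bound feature dimensionality.  Surfaces are expanded by a
  rule-based variant generator (lowercasing, regular head-word
  pluralization/singularization, hyphen/space alternation) — a
  documented, deterministic expander covering the variant classes that
  matter for lexicon lookup.
* from string→type occurrence records (`compile_majority_lexicon`): a
  type survives for a string iff it was assigned in at least half of the
  string's occurrences, boundary inclusive; occurrences are counted per
  record line.

Tagging against a lexicon is tokenization-aware: candidate token spans
(up to 8 tokens — beyond any realistic anatomical term, and a bound on
the span enumeration) are joined with single spaces, free-standing
hyphens collapse to spaces on both sides of the match, and comparison is
case-insensitive by default since it runs on truecased text.  Three
modes: `all` (every candidate; embedded relevant terms are never blocked
by longer irrelevant ones), `longest` (greedy leftmost-longest), and
`token` (single tokens only), plus an optional filter requiring a token
with an `NN*` POS tag in the span.  Matches become per-token
`DICT-B-<cat>` / `DICT-I-<cat>` features; the pipeline default is
`all` mode with no POS filter.

**Brown-cluster features.**  A word's position in a hard hierarchical
clustering is a bit string; its 4-, 6- and 10-digit prefixes name
increasingly coarse clusters and are emitted as features (on the
lowercased form, at offsets −1..+1).  When an identifier is shorter than
the prefix length the whole identifier is used.  Cluster maps are read
from the standard `bitstring TAB word [TAB count]` interchange TSV so
externally induced clusters drop in; the package also ships a greedy
agglomerative inducer (merge the pair maximizing class-bigram average
mutual information, bit strings from the merge tree, larger class takes
bit 0) — deterministic, intended for small vocabularies and
self-contained testing, not for corpus-scale induction.

**Local features.**  For each focus token, unigram features for surface
(truecased), normalized form (lowercased, digit runs collapsed to `0`),
lemma, POS and chunk at offsets −2..+2; same-family bigrams at adjacent
offsets (normalized form and POS by default); orthographic flags and a
collapsed word shape; character 2-/3-/4-grams with boundary sentinels
`^`/`$` at the focus.  Out-of-sentence offsets contribute boundary
features (`W[-2]=<S>`).  Morphosyntax comes either from supplied CoNLL
columns (`external`, the replication-quality path) or from a deliberately
simple deterministic builtin (closed-class lookup, suffix rules, plural
stripping, a one-pass NP chunker).

**Non-local features and two-stage tagging.**  Words tend to keep one
sense within a document, and an unambiguous mention elsewhere in the
document is evidence for an ambiguous one.  A first-stage model tags the
document; for every token, three statistics over all identically-spelled
tokens in the document (case-insensitive over truecased surfaces,
including the token itself) become features of a second-stage model: the
most frequent tag, the most frequent non-O tag (absent if none), and the
first occurrence's tag.  Tag ties break toward the earliest occurrence.
Second-stage *training* data is built by 10-fold cross-prediction: ten
first-stage models, each trained on nine folds, predict the features of
the held-out fold, so no model annotates a document it saw and gold
labels never leak into the features.

# Evaluation

Scores are mention-level precision, recall and F1, micro-averaged over
documents (macro- vs micro- is unstated in shared-task practice only
rarely; micro is the CoNLL convention and is what the package uses).
The primary criterion is **right-boundary match**: a prediction is
correct when its end offset (and, in the multiclass setting, its type —
exactly) equals a gold mention's.  Exact matching is available; since
mentions within a document are non-overlapping, end offsets are unique
and matching is one-to-one.  The single-class setting relabels every
mention to one type before matching.  By construction F(right-boundary) ≥
F(exact) and F(single-class) ≥ F(multiclass); both are property-tested.

# The synthetic corpus generator

Real corpora for this task are licensed downloads, so the package ships
a generator (`synth_config`, `generate_corpus`, `distort_case`)
reproducing the statistical structure each pipeline stage exploits:

* typed mentions planted at 26 per 1000 tokens (the density observed in
  large-scale literature tagging), drawn from a synthetic lexicon whose
  default size is 400 surfaces, 30% of them 2–3 token phrases;
* a small per-document surface pool (8 surfaces), giving the
  within-document repetition that non-local features need;
* document-level sense consistency: an ambiguous surface (30% of
  surfaces carry two types by default) keeps one type per document, and
  a type-specific cue word directly precedes a mention with probability
  0.9, guaranteed at least once per (document, ambiguous surface);
* a feature lexicon covering 70% of surfaces, so dictionary features are
  informative but imperfect, as with real resources;
* case distortion: sentence-initial capitalization, Title Case or
  ALL-UPPER headers, with the original forms recorded so restoration can
  be scored;
* gold POS/lemma/chunk columns, so feature tests run in external
  annotator mode.

Filler text is Zipf-distributed synthetic vocabulary (2000 words, a few
percent with acronym-like or capitalized canonical case); entity, cue and
filler vocabularies are disjoint by construction.  Everything is
deterministic given the seed.

What the generator does **not** emulate: real lexical statistics (entity
surfaces share character n-gram distributions with filler, so n-gram
features are weaker than on real text), morphological variation,
discontinuous or nested mentions, annotation noise, and genuinely
ambiguous case (two canonical casings of one lowercase form).  Passing
the synthetic recovery tests therefore demonstrates that the machinery —
features, training, decoding, non-local propagation — works end to end,
not that real-corpus F-scores are reproduced; on real corpora the
absolute numbers will differ.

# Numerical and design choices

* Character offsets are 0-based, half-open, counted in Unicode code
  points — the standoff convention of the formats read and written.
* Mention boundaries falling inside a token snap outward to token
  boundaries with a warning at encoding time (rejection is available).
* BIO (not BIOES) labeling throughout; invalid decoded sequences are
  repaired totally (`I-t` after `O` or a different type becomes `B-t`).
* Viterbi ties break toward the lower label index; cluster-merge and
  truecasing ties are documented above — every path is deterministic.
* L-BFGS runs to a relative-change tolerance with an iteration cap; the
  package default cap is 200.  The test suite and the acceptance script
  train with caps of 50–80 iterations on corpora of 40–400 documents
  (~600 tokens each at the main study condition) — on these problems the
  objective is flat past ~60 iterations, and held-out F changes only in
  the fourth digit.
* `anatag()` drops features seen fewer than twice in training
  (`min_feature_count = 2`), the conventional rare-feature cutoff of CRF
  taggers; `crf()` itself defaults to keeping everything.
* Dictionary matching enumerates spans per length with vectorized
  joining, so its cost is linear in tokens × max span.
* Unseen features at decode time contribute zero score; empty sentences
  decode to empty label sequences.

# Known limitations

* The builtin morphosyntactic annotator is a heuristic; replication-
  quality runs should supply external POS/lemma/chunk columns.
* The Brown inducer is O(V^4)-ish per merge schedule and is only meant
  for toy vocabularies; use externally induced cluster files at scale.
* Relation/event standoff lines (E/R), discontinuous mentions and nested
  mentions are out of scope; the reader rejects overlap rather than
  resolving it.
* The feature inventory is configurable but the shipped families are a
  reconstruction of standard NER practice; no claim is made that they
  match any particular system's undocumented template set.
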