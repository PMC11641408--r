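---
title: "Mining topical-fluoride perception from short-message corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining topical-fluoride perception from short-message corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluortweet)
```

## The problem

Public reluctance about topical fluoride (varnish, polish, fluoridated
toothpaste) is a live dental public-health issue: survey studies repeatedly
find a substantial minority of parents refusing fluoride applications for
their children. Social media offers a complementary, retrospective window on
those attitudes. `fluortweet` implements a complete content-analysis
pipeline for short-message corpora on this topic: keyword inclusion,
tokenization, near-duplicate elimination, expert-seeded categorization into
four content classes — posts voicing *concern*, posts reporting treatment
*experiences*, *positive* posts, *negative* posts — and trend and gender
statistics over a three-year window split into calendar quarters.

Because no public corpus accompanies the original study, the package ships a
synthetic-corpus generator with complete ground truth. Every stage of the
pipeline can therefore be validated by parameter recovery rather than by
comparison with an unavailable dataset.

## The model and its stages

### Inclusion and tokenization

A post enters the analysis when its raw text contains at least one of 15
keyword phrases (`default_keywords()`), matched as case-insensitive
contiguous substrings — the closest emulation of platform advanced-search
semantics. Matching happens *before* normalization, since the original
collection searched raw posts.

`normalize_text()` then applies a fixed 7-rule pipeline: strip one leading
`"RT @user:"` marker, remove URLs and `@mentions`, transliterate to ASCII
and lowercase, delete `#` (so hashtag words survive as plain words), replace
remaining non-alphanumerics with spaces, and split on whitespace. The source
method names only "tokenization", so this concrete rule set is this
package's fixed definition; the retweet rule is what makes a retweet
tokenize identically to its original, which the deduplication stage relies
on. There is deliberately no stemming and no stop-word removal: all
downstream comparison is of surface word forms.

### Word-level Levenshtein deduplication

The distance between two posts is the minimum number of single-*token*
insertions, deletions and substitutions transforming one token sequence into
the other (unit costs, no transpositions; tokens compared by exact
equality). The similarity score is

$$s(a,b) = 1 - \frac{d_{\mathrm{lev}}(a,b)}{\max(|a|,|b|)} \in [0,1],$$

with $s = 1$ for two empty sequences by convention. Normalizing by the
longer length keeps the score symmetric, bounded, and equal to 1 only for
exact equality.

`leader_cluster()` eliminates near-duplicates by a single greedy pass in
chronological order: each post joins the first existing cluster whose
*leader* is within the similarity threshold, else founds a new cluster. The
earliest exemplar of any repeated content is kept — originals precede their
retweets in time — and retained leaders are pairwise below threshold by
construction. The metric bound $d \ge ||a|-|b||$ gives a cheap upper bound
on similarity used to skip the dynamic programme; it is exactness-preserving.
Clusters reaching `min_cluster_size` (default 3) are flagged as probable
non-human content (advertisements, bot reposts); whether their leader is
also dropped is configurable (`drop_leaders`, default `FALSE`), because the
source procedure is ambiguous about whether one advertisement exemplar
survives. Finally `enforce_unique_authors()` keeps each author's earliest
post.

**Threshold.** The default similarity threshold is 0.8. The source method
states no numeric threshold; 0.8 cleanly separates exact and near copies
(retweets score 1.0 after normalization; advertisement variants with one
token changed in 10–14 score ≳ 0.9) from mere topical overlap, which on
unigram-rendered synthetic text stays far below 0.8.

### Seeded classification and inter-rater agreement

A random sample of posts (500 in the source design) is labelled
independently by two raters. Posts on which the raters agree form the *seed
set*; `build_seed_set()` enforces exactly two ratings per post from distinct
raters. Agreement is reported per category, one-vs-rest, as percent
agreement and Cohen's kappa $(p_o - p_e)/(1 - p_e)$ — per-category 2×2
kappas rather than a single 4-category kappa, matching how the source
reports a kappa per subcategory.

`classify_corpus()` assigns every remaining post to the category of its most
syntactically similar seed: the per-category score is the *maximum*
normalized similarity over that category's seeds (nearest-neighbour reading
of "most syntactic similarity"; a `mean_top_k` aggregation is available
behind a switch). Exact ties are broken by mean similarity over the tied
categories' seeds, then by the canonical category order
concern → experience → positive → negative, so classification is fully
deterministic. Scores below `confidence_floor` (default 0.1) are flagged
low-confidence rather than suppressed. Seed posts keep their consensus label
and are never re-scored.

### Statistics

* `build_quarter_series()` tabulates per-category counts over the 12
  half-open calendar quarters of the window \[2017-01-01, 2020-01-01).
* `describe_counts()` reports mean, sample SD ($n-1$), midpoint median, min,
  max — and a *truncated* mean, because the published "average per quarter"
  (1,792 from 21,511/12 = 1,792.58) is consistent only with truncation.
* `runs_test()` is the one-sample Wald–Wolfowitz test about the median
  (median ties dropped). For $n \le 30$ retained values the two-sided p
  comes from the closed-form run-count distribution,
  $p = \min(1,\, 2\min(P(R \le r), P(R \ge r)))$; larger samples use the
  normal approximation with continuity correction. The test detects
  non-randomness of a quarterly series; it says nothing about direction, so
  the pipeline reports it alongside the series itself rather than asserting
  "increase" from the test alone.
* `gender_chi_square()` tests gender-by-category tables among
  gender-identified posts only: an omnibus 2×4 Pearson test without
  continuity correction, and per-category 2×2 tests with Yates correction
  (toggleable), reported raw and Bonferroni-adjusted. Percentages use
  half-up rounding — one decimal for category shares, integers for gender
  shares — matching the printed conventions.

## The synthetic world

`generator_config()` states the world the analysis assumes; its defaults are
the published study conditions wherever those exist:

| parameter | default | why |
|---|---|---|
| `category_proportions` | 0.485 / 0.07 / 0.181 / 0.264 | the published corpus shares |
| `window_start`, `window_end` | 2017-01-01 → 2020-01-01 | the study window (12 quarters) |
| `gender_probs` | 0.75 / 0.12 / 0.13 | published female/male/undetermined shares |
| `trend` (concern) | 1.75 | first→last quarter weight ratio 2.75, matching the reported rise 478 → 1,315 |
| `trend` (experience, positive, negative) | 0 / 0.5 / 0.3 | flat experience; "limited increase" in negative; late surge in positive |
| `duplicate_fraction` | 0.2 | no stated desk-scale value; 0.2 is the canonical planted fraction exercised by the recovery experiments (the corpus-scale eliminated share, ≈ 0.84, is reachable by setting it) |
| `tweet_length` | 6–18 tokens | realistic short-post lengths |
| `vocab_size_per_category`, `shared_vocab_size` | 120 / 60 | disjoint stance vocabularies plus a shared topical pool |

Posts are rendered from a unigram bag-of-words model: tokens are drawn from
the post's category vocabulary (disjoint across categories) with probability
0.8 and from a shared pool with probability 0.2, with **Zipf (1/rank) word
weights**, one embedded study keyword per post, and an optional hashtag from
a pool with strongly separated planted frequencies. Zipf weighting matters:
it is both the standard empirical regularity of word frequencies and the
property that makes same-stance posts share high-frequency phrases, which is
exactly what nearest-seed lookup exploits on real text. (Uniform sampling,
by contrast, produces same-category posts with almost no token overlap and
makes the generator fail its own purpose of providing a recoverable truth.)

Retweet duplicates copy an original verbatim behind an `"RT @user:"` prefix
with a later timestamp; advertisement clusters are near-identical texts
(one filler token mutated, never the keyword) from distinct authors; a
small author-repeat rate (5%) plants the author multiplicity that
`enforce_unique_authors()` removes. Rater labels are simulated with
independent symmetric error: a rater reports the truth with probability
$1-e$, else a uniform other category, giving expected raw agreement
$(1-e_1)(1-e_2) + e_1 e_2/3$.

What the generator does **not** emulate: English syntax, sentiment lexicons,
bursty posting dynamics, account-level bot behaviour, or any coupling
between gender and category. A green recovery test therefore establishes
that the pipeline's machinery is correct on corpora with the assumed
statistical structure — not that the published substantive findings would
replicate on real platform data.

## Numerical choices and degenerate inputs

* Distances are integer dynamic programming (Rcpp); no floating-point
  tolerance is involved in clustering decisions beyond the threshold
  comparison `s >= threshold`.
* Tie-breaks everywhere are deterministic (chronology, then id;
  mean-similarity, then canonical category order).
* Empty token sequences: similarity 1 to another empty sequence, 0 to any
  non-empty one; an empty post classifies through the tie rule with score 0
  and a low-confidence flag.
* `runs_test()` errors when fewer than 2 values survive median-tie removal;
  a one-sided dichotomy (all above or all below) returns p = 1.
* Expected-count zeros make `chi_square_table()` fail loudly, naming the
  cell, rather than returning NaN.
* Percent reporting uses explicit half-up rounding, not `round()`'s
  banker's rounding.
* The pipeline config is structured JSON (`read_pipeline_config()`), echoed
  verbatim into the run report for provenance; JSON was chosen over YAML so
  the package has no dependency beyond its data-handling stack.

## Known limitations

* Greedy leader clustering is order-dependent by design (chronological
  first-fit); it is deterministic but not the globally optimal clustering.
* Keyword matching is plain substring search; "fluoride" inside a longer
  token (e.g. "fluoridealert") matches, which mirrors advanced-search
  behaviour but is not word-boundary-exact.
* The classifier is purely syntactic, by design fidelity: no embeddings, no
  TF-IDF. Its accuracy on real text depends entirely on how much surface
  vocabulary stances share.
* Gender is consumed as an input attribute; inferring it (the original study
  used an external classifier) is out of scope.
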