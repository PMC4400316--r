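---
title: "Mining pain-related microblog streams: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining pain-related microblog streams: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painstream)
```

`painstream` analyses short microblog posts that mention an emotive query
term (canonically *pain*) along three axes: what people say (term
co-occurrence communities), how they feel (hybrid lexicon/Naive-Bayes
sentiment), and how the posts travel (directed retweet/mention networks).
This vignette is the package's own account of the underlying models, the
tunable parameters and their defaults, the numerical choices, and the
limits of what the synthetic-data tests demonstrate.

## Corpus model

A corpus is an ordered tibble of tweet records (id, user, text, UTC
timestamp, optional city/coordinates/label) plus the query term. Three
reduction steps precede every analysis:

- **Deduplication.** Mass-reposted content (quotes, spam, song lyrics)
  would otherwise dominate both term counts and edge weights. Equality is
  case-folded, whitespace-collapsed raw text; the first occurrence is kept.
  We deliberately stop short of fuzzy matching: near-duplicates with small
  edits are genuine re-authorship and their shared phrasing is signal.
- **Tokenization.** Lowercase; URLs and `@mentions` removed (mentions are
  network edges, not terms); `#hashtag` folds to `hashtag`; punctuation is
  stripped except intra-word apostrophes, so contractions such as `don't`
  and `can't` — among the most frequent terms in emotive corpora — survive
  as single tokens; emoticons are preserved verbatim as tokens. A fixed
  packaged ~120-word stopword list is applied. The list **excludes all
  negators** (`no`, `not`, `never`, `don't`, …): negators rank among the
  top corpus terms and are the input to the sentiment negation rule, so
  stopwording them would corrupt both analyses. The query term itself is
  dropped for graph statistics (it would link every pair of terms) but
  retained for sentiment scoring (the lexicon may weight it); `tokenize()`
  exposes this as `drop_query`.
- **Hour localization.** Timestamps are shifted by fixed per-city UTC
  offsets — no daylight-saving rules, since city-level offsets at a single
  collection epoch are the only defensible assumption — and binned 1..24,
  where bin *h* covers *h*:00–*h*:59 and bin 24 covers 00:00–00:59 (the
  "at 2400" axis convention).

## Sentiment model

The classifier is a hybrid of a transparent rule and a trained model.

**Rule scorer.** Each token matching the lexicon contributes its signed
integer weight (−5..+5, AFINN dialect). If any negator occurs within the
**5 preceding tokens**, the keyword's contribution is reversed to a *unit*
score of the opposite sign (weight −2 under negation contributes +1, not
+2): negation in informal English flips polarity but rarely preserves
intensity. The window is preceding-only — English negation scopes forward
("not good", "don't feel great") — which also keeps the scan linear.
Emoticons contribute their weights and are never negated. Polarity is the
sign of the sum; confidence is `min(1, |score|/5)`, zero exactly when
nothing matched. The confidence formula is a package choice: it saturates
at a score magnitude of 5, the largest single-word weight in the lexicon
dialect.

**Naive Bayes.** Features are the top `k_features` terms (default 2000) by
document-frequency risk ratio with additive smoothing `s = 0.5`, ranked by
`max(RR, 1/RR)` so markers of *either* class rank first, ties broken
lexicographically for determinism. Each training document contributes its
term relative frequencies (count / document length) over the selected
features; class likelihoods are add-one-smoothed multinomial estimates of
the **class-mean** relative-frequency vectors. Using the class mean rather
than the class total makes the estimates invariant to duplicating the
training corpus, a property the package asserts in its tests. Prediction
is the standard multinomial posterior in log space; tokens outside the
feature set are ignored, and a stream matching no feature returns the
prior.

**Arbitration.** The rule decides whenever its score is nonzero; the NB
posterior decides otherwise, positive iff it exceeds 0.5, with an exact
0.5 classified negative so the binary output is total. Rule-first
arbitration is a package design choice (the component structure admits
several combinations): the rule is precise when it fires, and the model
covers the lexicon's silence. The hybrid output is deliberately binary —
no neutral class — matching how positive-sentiment proportions are
reported downstream.

**Agreement.** `cohens_kappa()` implements the two-rater closed form.
For three or more raters the field's reporting is ambiguous between two
generalizations, so `multi_rater_kappa()` returns both the mean pairwise
Cohen's kappa and Fleiss' kappa, labeled.

## Term graph and Louvain

Two terms are linked whenever they co-occur in a tweet, with **set
semantics**: a tweet contributes at most 1 to an edge regardless of token
repetition, because in ~140-character posts multiplicity is mostly noise.
Degree centrality is reported as the count of distinct neighbors, with
weighted degree available separately.

`louvain_communities()` is a from-scratch two-phase Louvain: greedy local
moves maximizing the modularity gain, then aggregation of communities into
super-nodes, repeated until a full pass improves `Q` by no more than
`tol = 1e-7`. Numerical choices: node visit order is shuffled
deterministically from the seed (and re-shuffled per level from
`seed + level`); gain ties go to the lowest community id; a move requires
a strict improvement beyond 1e-12 to avoid oscillation on symmetric
graphs. The reported `Q` is recomputed independently from the final
assignment on the original graph via the direct formula
`Q = Σ_c [ w_in(c)/W − γ(s_c/2W)² ]`, and the implementation asserts that
`Q` never decreases across passes. The resolution parameter γ (default 1)
is exposed; results in reports always quote `Q` at γ = 1.

Degenerate inputs: an edgeless graph yields singleton communities with
`Q = 0` (the formula's `W = 0` case is defined as 0); an empty graph is an
error.

## Geo-temporal aggregation

Per-group positive proportions come with the cross-group median. The
omnibus comparison across cities/hours is a Pearson chi-square of
homogeneity on the k×2 table without continuity correction — the standard
choice for unnamed "significant difference in proportions" claims — with a
warning attached when any expected cell drops below 1. Spearman
correlations use average ranks for ties and the t approximation with n−2
degrees of freedom for the two-sided p-value. City covariates are supplied
by the user in a documented CSV schema (population, density, median age,
education, income, poverty, percent uninsured, September mean high
temperature and precipitation days, latitude, longitude, UTC offset); the
package bundles no census or climate values. These correlations are
ecological: they relate city aggregates, not individuals, and the package's
reports make no causal claims.

## Mention networks

Mentions and retweets are merged into one directed edge type
(author → mentioned user, at most one edge per distinct handle per tweet,
self-mentions dropped); `retweets_only = TRUE` restricts to RT-prefixed
tweets. Diameter and average path length are computed **undirected on the
largest weakly connected component**: fragmented mention graphs only admit
per-component path statistics, and a single finite number for a fragmented
graph is only defined under such a convention, which the package logs here.
Density is computed on the simple directed graph, parallel mentions kept
as weights. Modularity communities reuse the package's Louvain on the
undirected weighted projection.

`compare_networks()` uses the Mann–Whitney U test: degree distributions
are heavily skewed, which is also why tiny rank effect sizes can coexist
with large mean differences; the effect size is `|Z|/√N` from the
tie-corrected normal approximation. For small untied samples (both n < 50)
the p-value comes from the exact U distribution instead, matching
exhaustive-enumeration oracles in the tests.

## Synthetic generator

The generator exists because the original study corpora for this kind of
analysis are typically never deposited; it emulates exactly the
statistical structure the analyses consume, with exhaustive ground truth:

- every tweet contains the query term; true-positive tweets carry 1–2
  positive marker tokens (weights ≥ +3 in the packaged lexicon sample) and
  true-negative tweets negative markers, so on clean tweets the rule
  scorer's verdict equals the planted label even with the query term's own
  weight (−2) included;
- topic words come from pairwise-disjoint planted communities, filler from
  a neutral vocabulary that carries no lexicon weight and is not
  stopworded, so tokenized counts reconcile exactly with the generator's
  bookkeeping;
- city and hour strata follow configurable weights, with per-city offsets
  to the positive share (defaults span 0.15 to 0.55 around a 0.30
  baseline, emulating the wide city spread reported for this kind of
  corpus at 1,500 tweets per city);
- with `negation_rate > 0`, positive tweets receive "not" immediately
  before a marker and flip their truth label, exercising the negation rule
  end to end;
- mention corpora realize a planted directed edge list — star (one
  high-in-degree hub), chain, or planted partition (within-block pair
  probability `p_in`, cross-block `p_out`, warning when
  `p_in ≤ p_out`) — as exactly one tweet per edge, "RT @user" with
  probability `p_retweet` (default 0.7) and a bare "@user" otherwise.

Default sizes follow the study conditions the package emulates: 1,500
tweets per search (the API cap the original collections ran under), a
30% baseline positive mixture, and 4 planted blocks of 50 users for
partition-recovery experiments. Tests use 10,000-tweet corpora for mixture
recovery (3-binomial-SD bands), 200-node planted partitions over 10 seeds
for Louvain recovery (ARI ≥ 0.9), and 100 null tables for chi-square
calibration; these sizes give the property checks stable statistics while
the full suite stays quick to run.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: linguistic realism (grammar, slang,
misspellings, sarcasm), heavy-tailed user activity, correlated topics and
sentiment, geolocation error, non-English text, and lexicon coverage gaps.
On real streams the rule scorer's accuracy is bounded by lexicon coverage
and the NB model by its training labels; the synthetic results certify the
machinery (estimators, graph algorithms, bookkeeping), not field accuracy.

## Known limitations

- The packaged lexicon is a ~130-term AFINN-dialect sample plus 20
  emoticons, sufficient for synthetic workflows; real analyses should load
  a full word list via `read_lexicon_tsv()`.
- No stemming, n-grams, or synonym handling in the term graph; these are
  natural extensions.
- Pure-R Louvain is comfortable to a few hundred thousand edges; far
  beyond that an igraph/C backend would be the right tool.
- Hour-of-day comparisons pool all cities by local hour; a
  stratified-by-city analysis would need the per-city tables that
  `proportion_by_group()` already provides.
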