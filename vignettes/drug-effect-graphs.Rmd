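---
title: "Drug-effect graphs for adverse-event mining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-effect graphs for adverse-event mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degmine)
```

## The model

An adverse drug event (ADE) is any undesirable physiological effect of a drug
beyond its intended therapeutic effect. Post-market ADE surveillance
traditionally relies on voluntary spontaneous-reporting systems, which are
slow and severely under-reported; social-media streams offer a complementary,
near-real-time signal, but the relevant information is buried in short, noisy
text and frequently spread across several posts by the same person.

`degmine` models drug–effect knowledge as a **drug-effect graph (DEG)**: a
bipartite graph whose partite sets are drugs \(D\) and effects \(S\), with an
edge \((d, e)\) recording an observed drug–effect relationship. Two DEGs play
complementary roles:

* **the reference DEG**, built from a SIDER-style relationship table
  (`load_sider()`); every recorded pair is an *adverse* edge;
* **the Twitter DEG**, built from user timelines: a drug mention and an
  effect mention by the same user within a temporal window of `t_window`
  days become an edge (`build_user_deg()`, `build_twitter_deg()`).

Because only positive examples are recorded, the negative class is
**pseudo-non-adverse**: pairs of existing nodes not recorded as adverse,
sampled uniformly without replacement (`sample_pseudo_negatives()`). The
label asserts absence of a record, not absence of an effect — a deliberate
weak-negative convention, which is also why edge classification scores are
useful for *hypothesis generation*: a "negative" pair scored like a positive
one is a candidate unrecorded ADE.

## Topological edge features

The pharmacological neighborhood \(\Gamma(x)\) of a node is every node within
two hops of \(x\), excluding \(x\) itself. In a bipartite graph this mixes
classes: for a drug it contains its effects (distance 1) and the drugs
sharing an effect with it (distance 2). \(\Gamma(x)\) never includes \(x\):
the definition of a *neighborhood* of \(x\) concerns other nodes, and
including \(x\) would inflate every index by a constant without adding
information.

For a queried pair \((d, e)\) the feature vector
(`featurize_edge()`) holds:

* the incident-edge degrees of \(d\) and \(e\) (one-hop counts, distinct
  from the two-hop \(|\Gamma|\) sizes);
* common-neighbor count \(N(d,e) = |\Gamma(d) \cap \Gamma(e)|\);
* Jaccard coefficient
  \(S(d,e) = |\Gamma(d) \cap \Gamma(e)| / |\Gamma(d) \cup \Gamma(e)|\),
  defined as 0 when both neighborhoods are empty (a 0/0 is "no shared
  structure", not missing data);
* Adamic–Adar index \(A(d,e) = \sum_z 1 / \ln |\Gamma(z)|\) over common
  nodes \(z\), skipping any \(z\) with \(|\Gamma(z)| \le 1\). The natural
  logarithm is used; the skip rule handles the \(\ln 1 = 0\) singularity —
  a degree-one common neighbor carries no discounting information and is
  dropped rather than allowed to contribute an infinity;
* preferential attachment \(PA(d,e) = |\Gamma(d)| \cdot |\Gamma(e)|\).

### The featurization convention

The queried pair need not be an edge. The package measures the graph **as
given**: recorded edges are featurized with themselves present (the query
edge is never removed), and sampled pseudo-negatives are featurized in their
absence. Hypothetical candidates are the one exception: at scoring time each
is *individually inserted, featurized, and removed*
(`classify_hypothetical()`), mirroring how a recorded edge looks to the
featurizer.

This asymmetry is substantive, not cosmetic. An edge bridges its two
endpoints, so for any present pair \(N(d,e) \ge \deg(d) + \deg(e) - 2\);
inserting *every* queried pair before measuring would hand that bridge to
positives and negatives alike and wash out exactly the neighborhood
structure the features exist to measure. Conversely, the bridge means that
edge membership itself is partly encoded in the features of present pairs —
so a classifier trained under this convention measures "does this pair look
like a recorded relationship *embedded in its neighborhood*", not the
neighborhood alone. Hypothesis scores should be read accordingly: insertion
grants every candidate the bridge, and the residual ranking signal comes
from the neighborhood context around it.

## The tweet pipeline

Entity extraction is dictionary-based (`extract_entities()`): a greedy
longest-match, case-insensitive scan over token n-grams (n up to 5) against
a lexicon mapping surface forms — including trade-name synonyms — to
canonical drug and effect identifiers, with a stop list suppressing
Twitter-ambiguous surfaces (the classic example being "pic", a picture on
Twitter but a valid medical acronym). The extractor is a contract: any
annotator producing (tweet, canonical id, class, span) mentions can replace
it. Repeated mentions of one canonical id within a tweet collapse to a
single mention to avoid double-counting in the downstream pairing;
the same entity in different tweets contributes separate mentions.

The experiential filter (`train_experiential_filter()`) separates posts
relating personal experience from spam/news/advertisements with a 10-tree
random forest over seven feature families: counts of hashtags, negation
words, URLs, pronouns, drug entities and effect entities, plus a raw
term-frequency bag of words. URLs and handles are counted before being
stripped by tokenization; hashtags keep their word part. The negation and
pronoun word lists are configurable (`default_negation_words()`,
`default_pronoun_words()`); the bag-of-words vocabulary keeps training
tokens with document frequency of at least 2. The labeled corpus is split
60/40, with 10-fold cross-validation on the training split for the reported
mean ± sd and a held-out evaluation on the rest.

### The temporal window

`t_window` (days, default 20) is the maximum calendar-day gap between a drug
mention and an effect mention for an edge to be drawn within one user's
history. Temporal distance is the absolute day difference — direction
agnostic, since users as often name the effect before the drug (and a
same-tweet co-mention is a legitimate distance-0 pair). Timestamps are
truncated to dates before differencing. An edge's `temporal_weight` is the
mean gap over **all** qualifying mention pairs of that (drug, effect), not
the nearest pair only: "average time between mentions" is a property of the
whole co-mention pattern, and the all-pairs mean is stable under repeated
mentions. Merging per-user graphs (`merge_degs()`) averages the temporal
weights of shared edges and sets `frequency_weight` to the number of
contributing users. `window_sweep()` tabulates edge counts as `t` grows
(total edges are non-decreasing by construction) to expose the operating
point where loosening the window mostly admits spurious pairs.

## Semantic context

**Sentiment.** Each tweet maps to the five-level scale
\(\{2, 1, 0, -1, -2\}\) (very positive … very negative). The scorer is a
pluggable function honoring that codomain; the shipped default counts
positive- minus negative-lexicon tokens and clamps to \([-2, 2]\). A
parse-tree neural scorer can be dropped in without touching the rest of the
pipeline — only the codomain and the averaging are load-bearing. The
sentiment context of an edge is the tuple \((S_d, S_e)\): the mean score
over contributing tweets mentioning the drug, and over those mentioning the
effect (a tweet mentioning both contributes to both). An endpoint with no
contributing tweet gets 0 with a warning — neutral, rather than missing.

**Topics.** Latent Dirichlet Allocation places entities in conversational
context: `fit_topic_model()` fits \(k\) topics (default 20) over exactly the
entity-bearing tweets. The estimator is a compact collapsed Gibbs sampler
written in the package (symmetric priors: document–topic \(\alpha = 1/k\),
topic–word \(\beta = 0.01\); 150 sweeps by default), seeded and fully
reproducible. Tweet topic vectors (`tweet_topic_vector()`) come from a
deterministic fixed-point fold-in against the fitted topic–word matrix;
a tweet whose tokens are all out-of-vocabulary returns the uniform vector —
the maximum-entropy choice for "no evidence". An entity's topic context is
the mean of the topic vectors of the tweets containing it, a point on the
k-simplex; an edge contributes the **concatenation** of its drug and effect
contexts (2k values). Concatenation rather than difference was chosen
because the classifier, not the feature, should decide how the two contexts
interact; a forest can represent differences but a difference cannot recover
the endpoints.

## Edge classification and enrichment

Four nested feature sets are evaluated (`edge_feature_matrix()`): `topo`
(Twitter-side topological features plus the two edge weights), `topo_sent`
(+ sentiment tuple), `topo_sent_topic` (+ 2k topic block) and `enriched`
(+ the reference graph's topological block for the same pair — the union of
the two graphs' views of one edge). The Twitter edge weights sit in the
baseline block because they are part of the Twitter graph's native edge
model. Enrichment of a pair with an endpoint absent from the reference graph
uses an all-zero block with `missing_sider_flag = 1`: zeros alone would be
indistinguishable from a genuinely isolated node, the flag keeps the two
cases separable.

The classifier is a 10-tree random forest (`train_edge_classifier()`), with
stratified 10-fold cross-validation (`cross_validate()`), seeded 50/50
train/test splits (`split_train_test()`), and precision / recall / F1
(`evaluate_predictions()`; precision is 0 by convention when nothing is
predicted positive). Hard labels use a 0.5 threshold on the ensemble vote
fraction; `classify_hypothetical()` exposes both the vote fraction and the
thresholded label, leaving the hypothesis-acceptance cutoff to the analyst.

## Synthetic test bed

Real SIDER snapshots and tweet collections are not redistributable, so the
package carries seeded generators that emulate their load-bearing structure:

* `generate_planted_sider()` partitions drugs and effects into
  pharmacological blocks and draws adverse edges with probability `p_in`
  within a block and `p_out` across (defaults 50 drugs × 100 effects, 5
  blocks, `p_in = 0.6`, `p_out = 0.02`). Block structure is a minimal stand-in
  for the co-morbidity clustering that makes adverse edges topologically
  recognizable; `p_in = p_out` removes the planted signal entirely.
* `generate_tweet_stream()` writes per-user timelines in which planted
  (drug, effect) pairs are co-mentioned at controlled day offsets (0–20 by
  default), each pair isolated in its own 60-day time cluster so the
  ground-truth **ledger** of intended edges and offsets is exact; lone
  spurious mentions and hashtag/URL spam exercise the window rule and the
  experiential filter. Tweet text is template English over synthetic
  surfaces, with sentiment words and block-specific topic vocabulary
  injected at configurable rates.
* `case_study_fixture()` is a permanently fixed 18-tweet, 9-user corpus
  illustrating the whole construction, with one user's star graph (4 nodes,
  3 edges of weight 2) and a merged graph of 3 drugs, 9 effects and
  unit frequency weights. Its canonical ids and its small SIDER-style
  labeling table are synthetic stand-ins.

What the generators do **not** emulate: natural language (templates only, so
the filter's measured accuracy says nothing about real-tweet linguistics),
misspellings and creative drug slang (the dictionary extractor is exercised
only on in-lexicon surfaces), bursty or missing posting behavior, multi-drug
narratives, and the heavy-tailed degree distributions of the real SIDER.
Passing tests demonstrate that the machinery is correct and that the method
recovers planted structure under its own assumptions — not that those
assumptions hold on the live stream.

## Numerical and scale choices

* Neighborhoods are computed from adjacency lists with a per-graph cache;
  inserting a candidate invalidates only \(\Gamma\) of the endpoints and of
  nodes one hop from them (a two-hop set can change only there), which keeps
  insert-and-classify linear in local degree. A brute-force depth-2 BFS
  oracle cross-checks every index in the tests.
* Pseudo-negative sampling is rejection-free index sampling over the
  complement of the adverse set, so it stays exact and fast even when the
  complement is small.
* Topic and context vectors are validated on the simplex to 1e-6; merged
  temporal weights match ledger means to 1e-9.
* Test problem sizes: the classification properties run at the generator
  defaults (150 nodes, ~1,400 labeled edges, 10 seeds); the balanced-set
  arithmetic runs at full reference scale (139,756 adverse edges) since it
  involves no featurization; oracle equivalence uses 1,000 random graphs of
  at most 30 nodes. LDA checks use two disjoint six-word vocabularies with
  six-token tweets, enough for a two-topic fit to place ≥ 0.9 mass correctly
  under the \(\alpha = 1/k\) fold-in prior.

## Limitations

Dictionary extraction cannot find what the lexicon does not contain, and the
pseudo-negative convention means reported precision is with respect to the
reference database, not ground truth. Sentiment defaults are deliberately
simple; swap in a stronger scorer for real analyses. The temporal window is
a population-level constant — no per-drug pharmacokinetics. Candidate scores
rank hypotheses for follow-up (corpus evidence via
`find_corpus_evidence()`, then the literature); they are not causal claims.
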