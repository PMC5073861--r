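# degmine

Pharmacovigilance tooling built around **drug-effect graphs (DEGs)** —
bipartite graphs whose partite sets are drugs *D* and physiological effects
*S*, with an edge (*d*, *e*) recording an observed drug–effect relationship.
The package is for researchers mining adverse drug events (ADEs) from social
media: it builds one DEG from a SIDER-style drug/side-effect table (every
recorded pair an *adverse* edge) and a second DEG from user tweet timelines,
classifies edges as adverse versus *pseudo-non-adverse*, and scores
hypothetical, as-yet-unrecorded drug–effect pairs.

## The method

For a pair (*d*, *e*), features are computed on the pharmacological
neighborhood Γ(*x*) — all nodes within two hops of *x* — namely the endpoint
degrees plus four link-prediction indices:

- common neighbors  N(d,e) = |Γ(d) ∩ Γ(e)|
- Jaccard coefficient  S(d,e) = |Γ(d) ∩ Γ(e)| / |Γ(d) ∪ Γ(e)|
- Adamic–Adar  A(d,e) = Σ_z 1 / ln|Γ(z)| over common nodes z with |Γ(z)| > 1
- preferential attachment  PA(d,e) = |Γ(d)| · |Γ(e)|

The Twitter-side graph is built per user: tweets pass an experiential filter
(10-tree random forest over hashtag/negation/URL/pronoun/entity counts and a
bag of words), drug and effect mentions are extracted with a synonym-aware
dictionary lexicon, and an edge is drawn when a drug and an effect are
mentioned within *t* = 20 days, weighted by the mean day gap and, after
merging users, by the number of contributing users. Edges can additionally
carry semantic context: a per-endpoint sentiment tuple on the
{2, 1, 0, −1, −2} scale and LDA topic contexts (k = 20 topics by default).
A 10-tree random forest separates adverse from pseudo-non-adverse edges;
hypothetical edges (D × S minus the recorded pairs) are individually
inserted, featurized, scored and removed.

## Worked example

The bundled 18-tweet, 9-user corpus illustrates the whole construction:

```r
library(degmine)

fx <- case_study_fixture()
histories <- extract_user_histories(fx$tweets, fx$lexicon)
g <- build_twitter_deg(histories, load_sider(fx$sider), t_window = 20)
g
#> <deg> 3 drugs, 9 effects, 11 edges
#>   labels: adverse=6, pseudo_non_adverse=5, unlabeled=0
attr(g, "n_user_graphs")
#> [1] 9
head(g$edges, 4)
#>   drug_id effect_id              label temporal_weight frequency_weight
#> 1 CID2802  C0009676            adverse               2                1
#> 2 CID2802  C0011570            adverse               2                1
#> 3 CID2802  C0030193 pseudo_non_adverse               2                1
#> 4 CID5865  C0162429            adverse               2                1
```

Nine users each contribute one small graph; user 1 mentions a benzodiazepine
on Feb 9 and three effects on Feb 11, so their star has three edges of
temporal weight 2. Every merged edge comes from a single user (frequency
weight 1), and labels follow presence in the reference table.

Edge classification on the planted-block synthetic reference graph
(50 drugs × 100 effects, 5 blocks, within/cross adverse edge probabilities
0.6 / 0.02, balanced with sampled pseudo-negatives, 50/50 split):

```r
gen <- generate_planted_sider(seed = 1)
balanced <- add_pseudo_negatives(gen$deg, seed = 2)
feats <- featurize_edges(gen$deg, balanced$edges[, c("drug_id", "effect_id")])
split <- split_train_test(nrow(feats), fraction = 0.5, seed = 3)
model <- train_edge_classifier(feats[split$train, ],
                               balanced$edges$label[split$train], seed = 4)
round(evaluate_predictions(predict(model, feats[split$test, ]),
                           balanced$edges$label[split$test]), 3)
#> precision    recall        f1
#>     0.917     0.974     0.945
```

Precision/recall are against the pseudo-negative convention: a "false
positive" is a pair absent from the reference, which is exactly what
`classify_hypothetical()` exploits to rank candidate unrecorded ADEs.

See `vignettes/drug-effect-graphs.Rmd` for the model, parameter and design
discussion.

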