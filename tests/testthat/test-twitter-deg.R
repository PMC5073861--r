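history_df <- function(user, classes, ids, dates) {
  data.frame(user_id = user, tweet_id = sprintf("t%02d", seq_along(ids)),
             date = as.Date(dates), canonical_id = ids,
             entity_class = classes, stringsAsFactors = FALSE)
}

test_that("a drug followed by three effects two days later gives a 4-node star", {
  fx <- case_study_fixture()
  histories <- extract_user_histories(fx$tweets, fx$lexicon)
  u1 <- build_user_deg(histories[["user1"]], t_window = 20L)
  expect_equal(nrow(u1$drugs) + nrow(u1$effects), 4L)
  expect_equal(nrow(u1$edges), 3L)
  expect_equal(u1$edges$temporal_weight, rep(2, 3L))
  expect_equal(unique(u1$edges$drug_id), "CID2802")
})

test_that("the temporal window rule admits and excludes pairs at the boundary", {
  h <- history_df("u", c("drug", "effect"), c("d1", "e1"),
                  c("2016-01-01", "2016-01-26"))  # 25 days apart
  expect_equal(nrow(build_user_deg(h, t_window = 20L)$edges), 0L)
  g25 <- build_user_deg(h, t_window = 25L)
  expect_equal(nrow(g25$edges), 1L)
  expect_equal(g25$edges$temporal_weight, 25)

  # drug-only history: no opposite-class partner, empty graph
  only_drugs <- history_df("u", c("drug", "drug"), c("d1", "d2"),
                           c("2016-01-01", "2016-01-02"))
  expect_equal(nrow(build_user_deg(only_drugs, t_window = 20L)$edges), 0L)

  # same-tweet co-mention: distance 0, edge allowed
  same_day <- history_df("u", c("drug", "effect"), c("d1", "e1"),
                         c("2016-01-01", "2016-01-01"))
  g0 <- build_user_deg(same_day, t_window = 1L)
  expect_equal(g0$edges$temporal_weight, 0)

  # direction-agnostic: effect before drug still pairs
  rev <- history_df("u", c("effect", "drug"), c("e1", "d1"),
                    c("2016-01-01", "2016-01-04"))
  expect_equal(build_user_deg(rev, t_window = 20L)$edges$temporal_weight, 3)
})

test_that("temporal weight is the all-pairs mean (brute-force oracle)", {
  set.seed(23)
  for (trial in 1:40) {
    n <- sample(2:10, 1L)
    h <- history_df(
      "u",
      sample(c("drug", "effect"), n, replace = TRUE),
      sample(c("d1", "d2", "e1", "e2"), n, replace = TRUE),
      as.Date("2016-01-01") + sample(0:40, n, replace = TRUE))
    # keep ids consistent with classes
    h$canonical_id <- ifelse(h$entity_class == "drug",
                             sub("^e", "d", h$canonical_id),
                             sub("^d", "e", h$canonical_id))
    t_win <- sample(1:25, 1L)
    got <- build_user_deg(h, t_window = t_win)$edges
    want <- brute_user_edges(h, t_win)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      got <- got[order(got$drug_id, got$effect_id), ]
      want <- want[order(want$drug_id, want$effect_id), ]
      expect_equal(got$temporal_weight, want$temporal_weight, tolerance = 1e-9)
    }
  }
})

test_that("build_twitter_deg merges users and labels against the reference", {
  h1 <- history_df("u1", c("drug", "effect"), c("d1", "e1"),
                   c("2016-01-01", "2016-01-03"))
  h2 <- history_df("u2", c("drug", "effect"), c("d1", "e1"),
                   c("2016-02-01", "2016-02-05"))
  sider <- load_sider(data.frame(drug_id = "d1", drug_name = "D",
                                 effect_id = "e1", effect_name = "E"))
  g <- build_twitter_deg(list(u1 = h1, u2 = h2), sider, t_window = 20L)
  expect_equal(g$edges$temporal_weight, 3)
  expect_equal(g$edges$frequency_weight, 2)
  expect_equal(g$edges$label, "adverse")
  expect_equal(attr(g, "n_user_graphs"), 2L)

  g2 <- build_twitter_deg(list(), sider)
  expect_equal(nrow(g2$edges), 0L)

  # an edge absent from the reference is pseudo-non-adverse
  h3 <- history_df("u3", c("drug", "effect"), c("d1", "e9"),
                   c("2016-01-01", "2016-01-02"))
  sider2 <- load_sider(data.frame(drug_id = "d1", drug_name = "D",
                                  effect_id = c("e1", "e9"),
                                  effect_name = c("E", "F")))
  sider2$edges$label[sider2$edges$effect_id == "e9"] <- "adverse"
  g3 <- build_twitter_deg(list(u1 = h1, u3 = h3), sider, t_window = 20L)
  expect_setequal(g3$edges$label[g3$edges$effect_id == "e9"],
                  "pseudo_non_adverse")
})

test_that("window sweep is monotone in t and reports adverse fractions", {
  fx <- case_study_fixture()
  histories <- extract_user_histories(fx$tweets, fx$lexicon)
  sider <- load_sider(fx$sider)
  sweep <- window_sweep(histories, sider, t_values = c(1L, 3L, 7L, 20L))
  expect_true(all(diff(sweep$total_edges) >= 0))
  expect_true(all(sweep$adverse_edges <= sweep$total_edges))
  expect_equal(sweep$pct_adverse,
               ifelse(sweep$total_edges == 0, 0,
                      sweep$adverse_edges / sweep$total_edges))
  # same-day co-mention present at t = 1
  expect_gte(sweep$total_edges[1L], 1L)
})
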