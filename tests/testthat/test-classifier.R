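test_that("precision/recall/F1 follow the stated conventions", {
  expect_equal(evaluate_predictions(c("a", "a", "b"), c("a", "a", "b"),
                                    positive = "a"),
               c(precision = 1, recall = 1, f1 = 1))
  # TP = 3, FP = 1, FN = 1
  pred <- c("a", "a", "a", "a", "b", "b")
  truth <- c("a", "a", "a", "b", "a", "b")
  expect_equal(evaluate_predictions(pred, truth, positive = "a"),
               c(precision = 0.75, recall = 0.75, f1 = 0.75))
  # no positive predictions -> precision 0 by convention
  expect_equal(evaluate_predictions(c("b", "b"), c("a", "b"), positive = "a"),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("evaluate matches an independent confusion-matrix tally", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    pred <- sample(c("adverse", "pseudo_non_adverse"), n, replace = TRUE)
    truth <- sample(c("adverse", "pseudo_non_adverse"), n, replace = TRUE)
    m <- evaluate_predictions(pred, truth)
    tp <- sum(pred == "adverse" & truth == "adverse")
    fp <- sum(pred == "adverse" & truth == "pseudo_non_adverse")
    fn <- sum(pred == "pseudo_non_adverse" & truth == "adverse")
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(unname(m), c(p, r, f))
  }
})

test_that("train/test splits are disjoint, exhaustive and seeded", {
  s <- split_train_test(2780L, fraction = 0.5, seed = 4)
  expect_length(s$train, 1390L)
  expect_length(s$test, 1390L)
  expect_length(intersect(s$train, s$test), 0L)
  expect_setequal(c(s$train, s$test), seq_len(2780L))
  expect_identical(split_train_test(2780L, 0.5, seed = 4), s)
  s2 <- split_train_test(100L, fraction = 0.6, seed = 4)
  expect_length(s2$train, 60L)
})

test_that("the edge classifier fits 10 trees, is seeded, and rejects one class", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60, mean = 0), ncol = 3),
             matrix(rnorm(60, mean = 6), ncol = 3))
  colnames(x) <- c("f1", "f2", "f3")
  y <- rep(c("pseudo_non_adverse", "adverse"), each = 20)
  m <- train_edge_classifier(x, y, seed = 1)
  expect_equal(m$model$ntree, 10)
  expect_equal(m$positive, "adverse")
  expect_equal(predict(m, x, type = "label"), y)  # separable: perfect training fit
  s1 <- predict(m, x, type = "score")
  expect_true(all(s1 >= 0 & s1 <= 1))
  m2 <- train_edge_classifier(x, y, seed = 1)
  expect_identical(predict(m2, x, type = "score"), s1)
  expect_error(train_edge_classifier(x, rep("adverse", 40), seed = 1),
               "single class")
})

test_that("cross-validation is stratified, seeded, and averages fold metrics", {
  set.seed(3)
  x <- rbind(matrix(rnorm(120, 0), ncol = 3), matrix(rnorm(120, 5), ncol = 3))
  colnames(x) <- paste0("f", 1:3)
  y <- rep(c("pseudo_non_adverse", "adverse"), each = 40)
  cv <- cross_validate(x, y, folds = 10L, seed = 9)
  expect_equal(unname(cv$mean), c(1, 1, 1))
  expect_equal(unname(cv$sd), c(0, 0, 0))
  expect_equal(colMeans(cv$folds), cv$mean, tolerance = 1e-12)
  cv2 <- cross_validate(x, y, folds = 10L, seed = 9)
  expect_identical(cv$folds, cv2$folds)
})

test_that("feature blocks nest across the four selector configurations", {
  fx <- case_study_fixture()
  histories <- extract_user_histories(fx$tweets, fx$lexicon)
  sider <- load_sider(fx$sider)
  g <- build_twitter_deg(histories, sider, t_window = 20L)
  ctx <- semantic_context(g, fx$tweets, fx$lexicon, t_window = 20L,
                          k = 3L, seed = 6, iterations = 60L)

  base <- edge_feature_matrix(g, "topo")
  withsent <- edge_feature_matrix(g, "topo_sent", sentiment = ctx$sentiment)
  withtopic <- edge_feature_matrix(g, "topo_sent_topic",
                                   sentiment = ctx$sentiment, topic = ctx$topic)
  enriched <- edge_feature_matrix(g, "enriched", deg_sider = sider,
                                  sentiment = ctx$sentiment, topic = ctx$topic)

  base_cols <- c("degree_d", "degree_e", "common_neighbors", "jaccard",
                 "adamic_adar", "pref_attach", "temporal_weight",
                 "frequency_weight")
  expect_true(all(base_cols %in% names(base)))
  expect_true(all(names(base) %in% names(withsent)))
  expect_true(all(names(withsent) %in% names(withtopic)))
  expect_true(all(names(withtopic) %in% names(enriched)))
  expect_equal(setdiff(names(withsent), names(base)), c("s_drug", "s_effect"))
  expect_length(setdiff(names(withtopic), names(withsent)), 2L * 3L)

  expect_error(edge_feature_matrix(g, "topo_sent"), "sentiment")
  expect_error(edge_feature_matrix(g, "topo_sent_topic",
                                   sentiment = ctx$sentiment), "topic")
  expect_error(edge_feature_matrix(g, "enriched", sentiment = ctx$sentiment,
                                   topic = ctx$topic), "deg_sider")
})

test_that("enrichment equals direct reference-graph featurization or the sentinel", {
  fx <- case_study_fixture()
  histories <- extract_user_histories(fx$tweets, fx$lexicon)
  sider <- load_sider(fx$sider)
  g <- build_twitter_deg(histories, sider, t_window = 20L)
  ctx <- semantic_context(g, fx$tweets, fx$lexicon, t_window = 20L,
                          k = 2L, seed = 6, iterations = 40L)
  enriched <- edge_feature_matrix(g, "enriched", deg_sider = sider,
                                  sentiment = ctx$sentiment, topic = ctx$topic)
  sider_cols <- paste0("sider_", c("degree_d", "degree_e", "common_neighbors",
                                   "jaccard", "adamic_adar", "pref_attach"))
  for (r in seq_len(nrow(enriched))) {
    d <- enriched$drug_id[r]
    e <- enriched$effect_id[r]
    present <- d %in% sider$drugs$id && e %in% sider$effects$id
    if (present) {
      expect_equal(enriched$missing_sider_flag[r], 0)
      expect_equal(unname(unlist(enriched[r, sider_cols])),
                   unname(featurize_edge(sider, d, e, insert = FALSE)))
    } else {
      expect_equal(enriched$missing_sider_flag[r], 1)
      expect_equal(unname(unlist(enriched[r, sider_cols])), rep(0, 6))
    }
  }
  # the case-study graph has endpoints missing from its mini reference table
  expect_true(any(enriched$missing_sider_flag == 1))
  expect_true(any(enriched$missing_sider_flag == 0))
})
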