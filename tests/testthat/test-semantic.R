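test_that("the default lexicon scorer counts and clamps to the 5-level scale", {
  expect_equal(score_sentiment(""), 0L)
  expect_equal(score_sentiment("love this great stuff"), 2L)
  expect_equal(score_sentiment("love love great good better"), 2L)  # clamped
  expect_equal(score_sentiment("this is awful and terrible and the worst"), -2L)
  expect_equal(score_sentiment("good but awful"), 0L)
  # custom scorer with the "very negative" level passes through
  expect_equal(score_sentiment("whatever", scorer = function(t) -2L), -2L)
  expect_error(score_sentiment("x", scorer = function(t) 5L), "codomain")
})

test_that("edge sentiment averages per endpoint over contributing tweets", {
  # one tweet scoring +1 that mentions both endpoints -> (1, 1)
  both <- data.frame(text = "love my meds", mentions_drug = TRUE,
                     mentions_effect = TRUE)
  expect_equal(edge_sentiment(both), c(s_drug = 1, s_effect = 1))

  # drug tweets scoring {1, -1} -> 0; effect tweets {2, 1, 0} -> 1
  tweets <- data.frame(
    text = c("love it", "hate it", "great and amazing relief", "good stuff",
             "nothing to report"),
    mentions_drug = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    mentions_effect = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  s <- edge_sentiment(tweets)
  expect_equal(s[["s_drug"]], 0)
  expect_equal(s[["s_effect"]], 1)

  # missing endpoint coverage -> 0 with a warning
  drug_only <- data.frame(text = "love it", mentions_drug = TRUE,
                          mentions_effect = FALSE)
  expect_warning(s2 <- edge_sentiment(drug_only), "effect")
  expect_equal(s2[["s_effect"]], 0)

  # permutation invariance
  perm <- tweets[c(4, 1, 5, 3, 2), ]
  expect_equal(edge_sentiment(perm), s)
})

test_that("topic model honors the simplex contracts and the k = 1 degenerate case", {
  texts <- c("alpha beta gamma", "beta gamma delta", "alpha delta")
  m1 <- fit_topic_model(texts, k = 1L, seed = 3)
  expect_equal(tweet_topic_vector(m1, texts[1]), 1)
  expect_equal(entity_topic_context(m1, texts), 1)

  m <- fit_topic_model(texts, k = 3L, seed = 3)
  expect_equal(rowSums(m$topic_word), rep(1, 3), tolerance = 1e-6)
  for (t in texts) {
    th <- tweet_topic_vector(m, t)
    expect_true(all(th >= 0))
    expect_equal(sum(th), 1, tolerance = 1e-6)
  }
  # out-of-vocabulary tweet falls back to the uniform vector
  expect_equal(tweet_topic_vector(m, "zzz qqq"), rep(1 / 3, 3))
  expect_error(fit_topic_model(character(0), k = 2L, seed = 1), "empty corpus")
})

test_that("topic fits are seed-deterministic", {
  texts <- c("aspirin relief morning", "rash itch evening",
             "aspirin dose morning", "itch cream rash")
  a <- fit_topic_model(texts, k = 2L, seed = 11)
  b <- fit_topic_model(texts, k = 2L, seed = 11)
  expect_identical(a$topic_word, b$topic_word)
})

test_that("two disjoint vocabularies are recovered with >= 0.9 topic mass", {
  set.seed(21)
  vocab_a <- paste0("mood", 1:8)
  vocab_b <- paste0("skin", 1:8)
  mk <- function(v) paste(sample(v, 6L, replace = TRUE), collapse = " ")
  texts_a <- replicate(25L, mk(vocab_a))
  texts_b <- replicate(25L, mk(vocab_b))
  model <- fit_topic_model(c(texts_a, texts_b), k = 2L, seed = 8)
  theta_a <- vapply(texts_a, function(t) max(tweet_topic_vector(model, t)), 0)
  theta_b <- vapply(texts_b, function(t) max(tweet_topic_vector(model, t)), 0)
  expect_true(all(theta_a >= 0.9))
  expect_true(all(theta_b >= 0.9))
  # and the two groups sit on different topics
  top_a <- which.max(tweet_topic_vector(model, texts_a[1]))
  top_b <- which.max(tweet_topic_vector(model, texts_b[1]))
  expect_false(top_a == top_b)

  # entity context is the mean of its tweets' vectors
  c1 <- entity_topic_context(model, texts_a[1:2])
  manual <- (tweet_topic_vector(model, texts_a[1]) +
               tweet_topic_vector(model, texts_a[2])) / 2
  expect_equal(c1, manual, tolerance = 1e-12)
  expect_equal(sum(c1), 1, tolerance = 1e-6)

  two <- entity_topic_context(model, c(texts_a[1], texts_b[1]))
  expect_equal(sum(two), 1, tolerance = 1e-6)
  expect_error(entity_topic_context(model, character(0)), "no containing tweets")
})

test_that("semantic_context assembles per-edge sentiment and per-entity topics", {
  fx <- case_study_fixture()
  histories <- extract_user_histories(fx$tweets, fx$lexicon)
  g <- build_twitter_deg(histories, load_sider(fx$sider), t_window = 20L)
  ctx <- semantic_context(g, fx$tweets, fx$lexicon, t_window = 20L,
                          k = 4L, seed = 2, iterations = 60L)
  expect_equal(nrow(ctx$sentiment), nrow(g$edges))
  expect_true(all(abs(ctx$sentiment$s_drug) <= 2))
  expect_true(all(abs(ctx$sentiment$s_effect) <= 2))
  expect_setequal(rownames(ctx$topic$drug), g$drugs$id)
  expect_setequal(rownames(ctx$topic$effect), g$effects$id)
  sums <- c(rowSums(ctx$topic$drug), rowSums(ctx$topic$effect))
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-6)
})
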