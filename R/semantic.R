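#' Default sentiment word lists
#'
#' The shipped lexicon scorer counts positive and negative tokens; both lists
#' are configurable.
#'
#' @return Character vector of lowercase words.
#' @export
default_positive_words <- function() {
  c("love", "like", "great", "good", "better", "relief", "relieved",
    "awesome", "amazing", "happy", "glad", "best", "works", "helped",
    "thanks", "wonderful", "fine", "calm")
}

#' @rdname default_positive_words
#' @export
default_negative_words <- function() {
  c("hate", "horrible", "awful", "terrible", "worse", "worst", "bad",
    "sick", "ugh", "hurts", "tired", "kill", "sad", "cry", "miserable",
    "complicated", "annoying")
}

sentiment_codomain <- c(-2L, -1L, 0L, 1L, 2L)

#' Lexicon sentiment scorer
#'
#' Builds a scorer mapping a text to the five-level sentiment scale
#' \{2, 1, 0, -1, -2\} (very positive ... very negative): the raw score is the
#' number of positive-list tokens minus the number of negative-list tokens,
#' clamped to \[-2, 2\]. Any function honoring the same codomain can replace
#' it wherever a `scorer` argument is accepted.
#'
#' @param positive,negative Word lists.
#' @return A function `text -> integer`.
#' @export
lexicon_sentiment_scorer <- function(positive = default_positive_words(),
                                     negative = default_negative_words()) {
  force(positive); force(negative)
  function(text) {
    toks <- analyze_text(text)$tokens
    raw <- sum(toks %in% positive) - sum(toks %in% negative)
    as.integer(max(-2L, min(2L, raw)))
  }
}

#' Score the sentiment of one tweet
#'
#' @param text Tweet text.
#' @param scorer A sentiment function `text -> {2, 1, 0, -1, -2}`; defaults to
#'   [lexicon_sentiment_scorer()].
#' @return Integer in \{2, 1, 0, -1, -2\}.
#' @export
score_sentiment <- function(text, scorer = lexicon_sentiment_scorer()) {
  v <- scorer(text)
  if (length(v) != 1L || is.na(v) || !v %in% sentiment_codomain) {
    stop("scorer output outside the {2, 1, 0, -1, -2} codomain: ", v,
         call. = FALSE)
  }
  as.integer(v)
}

#' Sentiment context of an edge
#'
#' The sentiment context of a (drug, effect) edge is the tuple
#' (`s_drug`, `s_effect`): `s_drug` is the mean sentiment score over the
#' contributing tweets that mention the drug, `s_effect` over those that
#' mention the effect. A tweet mentioning both endpoints contributes to both
#' means. When no contributing tweet covers an endpoint that component is 0
#' (with a warning).
#'
#' @param contributing_tweets Data frame with columns `text`,
#'   `mentions_drug`, `mentions_effect` (logical): the tweets whose mentions
#'   created the edge.
#' @inheritParams score_sentiment
#' @return Named numeric vector `c(s_drug =, s_effect =)`, each in \[-2, 2\].
#' @export
edge_sentiment <- function(contributing_tweets, scorer = lexicon_sentiment_scorer()) {
  stopifnot(is.data.frame(contributing_tweets),
            all(c("text", "mentions_drug", "mentions_effect") %in%
                  names(contributing_tweets)))
  scores <- vapply(contributing_tweets$text, score_sentiment, 0L,
                   scorer = scorer, USE.NAMES = FALSE)
  side_mean <- function(sel, side) {
    if (!any(sel)) {
      warning("no contributing tweet mentions the ", side,
              "; sentiment component set to 0", call. = FALSE)
      return(0)
    }
    mean(scores[sel])
  }
  c(s_drug = side_mean(contributing_tweets$mentions_drug, "drug"),
    s_effect = side_mean(contributing_tweets$mentions_effect, "effect"))
}

#' Fit an LDA topic model on an entity-bearing tweet corpus
#'
#' Latent Dirichlet Allocation fitted by collapsed Gibbs sampling with
#' symmetric priors (document-topic prior `alpha = 1/k`, topic-word prior
#' `beta = 0.01` by default). The corpus is intended to be exactly the tweets
#' containing at least one drug or effect mention. Reproducible from `seed`.
#'
#' @param texts Non-empty character vector of tweet texts.
#' @param k Number of topics (default 20).
#' @param seed Integer seed.
#' @param iterations Gibbs sweeps (default 150).
#' @param alpha,beta Dirichlet hyperparameters; `alpha = NULL` uses `1/k`.
#' @return An object of class `"topic_model"` with the vocabulary and the
#'   `k x V` topic-word matrix `topic_word` (rows sum to 1).
#' @export
fit_topic_model <- function(texts, k = 20L, seed, iterations = 150L,
                            alpha = NULL, beta = 0.01) {
  k <- as.integer(k)
  stopifnot(k >= 1L, iterations >= 1L)
  if (!length(texts)) stop("empty corpus", call. = FALSE)
  alpha <- alpha %||% (1 / k)
  docs <- lapply(texts, function(t) analyze_text(t)$tokens)
  vocab <- sort(unique(unlist(docs)))
  if (!length(vocab)) stop("corpus contains no tokens", call. = FALSE)
  v <- length(vocab)
  w <- unlist(lapply(docs, function(d) match(d, vocab)), use.names = FALSE)
  d <- rep(seq_along(docs), lengths(docs))
  n_tok <- length(w)
  local_seed(seed, {
    z <- sample.int(k, n_tok, replace = TRUE)
    nwz <- matrix(0, nrow = v, ncol = k)
    ndz <- matrix(0, nrow = length(docs), ncol = k)
    nz <- numeric(k)
    for (i in seq_len(n_tok)) {
      nwz[w[i], z[i]] <- nwz[w[i], z[i]] + 1
      ndz[d[i], z[i]] <- ndz[d[i], z[i]] + 1
      nz[z[i]] <- nz[z[i]] + 1
    }
    if (k > 1L) {
      for (it in seq_len(iterations)) {
        for (i in seq_len(n_tok)) {
          zi <- z[i]; wi <- w[i]; di <- d[i]
          nwz[wi, zi] <- nwz[wi, zi] - 1
          ndz[di, zi] <- ndz[di, zi] - 1
          nz[zi] <- nz[zi] - 1
          p <- (nwz[wi, ] + beta) * (ndz[di, ] + alpha) / (nz + v * beta)
          zi <- sample.int(k, 1L, prob = p)
          z[i] <- zi
          nwz[wi, zi] <- nwz[wi, zi] + 1
          ndz[di, zi] <- ndz[di, zi] + 1
          nz[zi] <- nz[zi] + 1
        }
      }
    }
    topic_word <- t(nwz) + beta
    topic_word <- topic_word / rowSums(topic_word)
    colnames(topic_word) <- vocab
    structure(list(k = k, vocab = vocab, topic_word = topic_word,
                   alpha = alpha, beta = beta, iterations = iterations),
              class = "topic_model")
  })
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> k = %d topics over %d terms\n", x$k, length(x$vocab)))
  invisible(x)
}

#' Topic vector of a tweet
#'
#' Folds a tweet into a fitted [fit_topic_model()] by deterministic fixed-point
#' iteration on the document-topic posterior: token responsibilities are
#' computed from the topic-word matrix and the current theta, and theta is
#' re-estimated with the `alpha` prior until convergence. Tweets whose tokens
#' are all out-of-vocabulary return the uniform vector.
#'
#' @param model A `"topic_model"`.
#' @param text Tweet text.
#' @param iterations Maximum fixed-point iterations.
#' @return Non-negative numeric vector of length `k` summing to 1.
#' @export
tweet_topic_vector <- function(model, text, iterations = 100L) {
  stopifnot(inherits(model, "topic_model"))
  k <- model$k
  toks <- analyze_text(text)$tokens
  wi <- match(toks, model$vocab)
  wi <- wi[!is.na(wi)]
  if (!length(wi)) return(rep(1 / k, k))
  if (k == 1L) return(1)
  phi <- model$topic_word[, wi, drop = FALSE]  # k x n_tokens
  theta <- rep(1 / k, k)
  for (it in seq_len(iterations)) {
    resp <- phi * theta
    resp <- sweep(resp, 2L, colSums(resp), "/")
    new_theta <- model$alpha + rowSums(resp)
    new_theta <- new_theta / sum(new_theta)
    if (max(abs(new_theta - theta)) < 1e-12) {
      theta <- new_theta
      break
    }
    theta <- new_theta
  }
  theta
}

#' Topic context of an entity
#'
#' The component-wise mean of the topic vectors of all tweets containing the
#' entity; a point on the k-simplex.
#'
#' @param model A `"topic_model"`.
#' @param texts Texts of the tweets containing the entity (at least one).
#' @return Numeric vector of length `k` summing to 1.
#' @export
entity_topic_context <- function(model, texts) {
  if (!length(texts)) stop("entity has no containing tweets", call. = FALSE)
  thetas <- vapply(texts, function(t) tweet_topic_vector(model, t),
                   numeric(model$k), USE.NAMES = FALSE)
  if (model$k == 1L) return(1)
  rowMeans(matrix(thetas, nrow = model$k))
}

#' Semantic context features for the edges of a Twitter DEG
#'
#' Convenience wrapper computing, for every edge of `deg_twitter`, the
#' sentiment tuple from the edge's contributing tweets and the topic contexts
#' of its two endpoints (each entity's context averaged over all tweets
#' mentioning it). The topic model is fitted on the entity-bearing tweets.
#'
#' @param deg_twitter A [deg] from [build_twitter_deg()].
#' @param tweets The tweet corpus (columns `tweet_id`, `user_id`, `date`,
#'   `text`).
#' @param lex The [lexicon()] used to build the graph.
#' @param t_window Window used to decide which tweets contribute to an edge.
#' @param k,seed,iterations Passed to [fit_topic_model()].
#' @param scorer Sentiment scorer.
#' @return List with `sentiment` (data frame `drug_id`, `effect_id`, `s_drug`,
#'   `s_effect`), `topic` (list of matrices `drug`, `effect`, rows = entity
#'   ids, `k` columns) and the fitted `model`.
#' @export
semantic_context <- function(deg_twitter, tweets, lex, t_window = 20L,
                             k = 20L, seed, iterations = 150L,
                             scorer = lexicon_sentiment_scorer()) {
  mentions <- extract_entities(tweets, lex)
  idx <- match(mentions$tweet_id, tweets$tweet_id)
  mentions$date <- tweets$date[idx]
  mentions$user_id <- tweets$user_id[idx]
  entity_tweets <- unique(mentions$tweet_id)
  if (!length(entity_tweets)) stop("no entity-bearing tweets", call. = FALSE)
  corpus <- tweets[tweets$tweet_id %in% entity_tweets, , drop = FALSE]
  model <- fit_topic_model(corpus$text, k = k, seed = seed,
                           iterations = iterations)
  theta_by_tweet <- lapply(stats::setNames(corpus$text, corpus$tweet_id),
                           function(t) tweet_topic_vector(model, t))
  ids <- unique(mentions$canonical_id)
  ctx <- t(vapply(ids, function(id) {
    tw <- unique(mentions$tweet_id[mentions$canonical_id == id])
    th <- vapply(theta_by_tweet[tw], identity, numeric(model$k))
    rowMeans(matrix(th, nrow = model$k))
  }, numeric(model$k)))
  if (model$k == 1L) ctx <- matrix(ctx, ncol = 1L, dimnames = list(ids, NULL))
  drug_ids <- ids[ids %in% deg_twitter$drugs$id]
  effect_ids <- ids[ids %in% deg_twitter$effects$id]
  topic <- list(drug = ctx[drug_ids, , drop = FALSE],
                effect = ctx[effect_ids, , drop = FALSE])
  sent <- edge_sentiment_table(deg_twitter, mentions, tweets, t_window, scorer)
  list(sentiment = sent, topic = topic, model = model)
}

# Per-edge contributing tweets: tweets with a mention of either endpoint whose
# (drug, effect) mention pair lies within the window for the edge's user(s).
edge_sentiment_table <- function(deg_twitter, mentions, tweets, t_window, scorer) {
  scores <- vapply(stats::setNames(tweets$text, tweets$tweet_id),
                   score_sentiment, 0L, scorer = scorer)
  edges <- deg_twitter$edges
  out <- edges[, c("drug_id", "effect_id")]
  out$s_drug <- 0
  out$s_effect <- 0
  for (r in seq_len(nrow(edges))) {
    dmen <- mentions[mentions$canonical_id == edges$drug_id[r] &
                       mentions$entity_class == "drug", , drop = FALSE]
    emen <- mentions[mentions$canonical_id == edges$effect_id[r] &
                       mentions$entity_class == "effect", , drop = FALSE]
    grid <- expand.grid(i = seq_len(nrow(dmen)), j = seq_len(nrow(emen)))
    same_user <- dmen$user_id[grid$i] == emen$user_id[grid$j]
    in_window <- abs(as.numeric(dmen$date[grid$i] - emen$date[grid$j])) <= t_window
    keep <- same_user & in_window
    d_tweets <- unique(dmen$tweet_id[grid$i[keep]])
    e_tweets <- unique(emen$tweet_id[grid$j[keep]])
    out$s_drug[r] <- if (length(d_tweets)) mean(scores[d_tweets]) else 0
    out$s_effect[r] <- if (length(e_tweets)) mean(scores[e_tweets]) else 0
  }
  out
}
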