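#' Enumerate hypothetical (unrecorded) drug-effect edges
#'
#' The hypothetical edge set is the full bipartite product of the graph's
#' drugs and effects minus the pairs already recorded as adverse.
#'
#' @param x A [deg].
#' @return Data frame with columns `drug_id`, `effect_id`; exactly
#'   `|D| * |S| - |adverse edges|` rows.
#' @export
enumerate_hypothetical_edges <- function(x) {
  stopifnot(inherits(x, "deg"))
  nd <- nrow(x$drugs)
  ne <- nrow(x$effects)
  adverse <- x$edges[x$edges$label == "adverse", , drop = FALSE]
  if (!nd || !ne) {
    return(data.frame(drug_id = character(), effect_id = character(),
                      stringsAsFactors = FALSE))
  }
  di <- match(adverse$drug_id, x$drugs$id)
  ei <- match(adverse$effect_id, x$effects$id)
  taken <- logical(nd * ne)
  taken[(di - 1L) * ne + ei] <- TRUE
  idx <- which(!taken)
  data.frame(drug_id = x$drugs$id[(idx - 1L) %/% ne + 1L],
             effect_id = x$effects$id[(idx - 1L) %% ne + 1L],
             stringsAsFactors = FALSE)
}

#' @rdname enumerate_hypothetical_edges
#' @return `count_hypothetical_edges` returns the count without
#'   materializing the pairs.
#' @export
count_hypothetical_edges <- function(x) {
  stopifnot(inherits(x, "deg"))
  as.double(nrow(x$drugs)) * nrow(x$effects) - sum(x$edges$label == "adverse")
}

#' Insert-and-classify hypothetical edges
#'
#' Each candidate pair is individually inserted into the graph, featurized,
#' scored by the trained classifier and removed; the graph is unchanged
#' afterwards. Insertion mirrors how recorded adverse edges are featurized at
#' training time (present in their own neighborhood). Scores are
#' positive-class vote fractions.
#'
#' @param x The reference [deg] (e.g. the SIDER graph).
#' @param model An [train_edge_classifier()] model whose features are the
#'   topological block of `x`.
#' @param candidates Data frame `drug_id`, `effect_id`; defaults to the full
#'   [enumerate_hypothetical_edges()] set. Both endpoints must exist in `x`.
#' @param sort Sort the result by decreasing score (default `TRUE`).
#' @return Data frame `drug_id`, `effect_id`, `score`, `predicted_label`.
#' @export
classify_hypothetical <- function(x, model, candidates = NULL, sort = TRUE) {
  stopifnot(inherits(x, "deg"), inherits(model, "edge_classifier"))
  candidates <- candidates %||% enumerate_hypothetical_edges(x)
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  feats <- featurize_edges(x, candidates, insert = TRUE)
  out <- candidates[, c("drug_id", "effect_id")]
  out$score <- predict(model, feats, type = "score")
  out$predicted_label <- predict(model, feats, type = "label")
  if (sort) out <- out[order(-out$score, out$drug_id, out$effect_id), ]
  rownames(out) <- NULL
  out
}

#' Search a tweet corpus for evidence of candidate ADEs
#'
#' For each candidate (drug, effect) pair, finds the users who mention both
#' the drug and the effect within `t_window` days, reporting the witnessing
#' tweet pair with the smallest day gap per user.
#'
#' @param candidates Data frame with columns `drug_id`, `effect_id`.
#' @param tweets Tweet corpus (columns `tweet_id`, `user_id`, `date`, `text`).
#' @param lex A [lexicon()].
#' @param t_window Window length in days (default 20).
#' @return Data frame with one row per (candidate, user) evidence hit:
#'   `drug_id`, `effect_id`, `user_id`, `drug_tweet_id`, `effect_tweet_id`,
#'   `day_gap`.
#' @export
find_corpus_evidence <- function(candidates, tweets, lex, t_window = 20L) {
  empty <- data.frame(drug_id = character(), effect_id = character(),
                      user_id = character(), drug_tweet_id = character(),
                      effect_tweet_id = character(), day_gap = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(tweets) || !nrow(candidates)) return(empty)
  mentions <- extract_entities(tweets, lex)
  if (!nrow(mentions)) return(empty)
  idx <- match(mentions$tweet_id, tweets$tweet_id)
  mentions$user_id <- tweets$user_id[idx]
  mentions$date <- tweets$date[idx]
  rows <- list()
  for (r in seq_len(nrow(candidates))) {
    dmen <- mentions[mentions$canonical_id == candidates$drug_id[r] &
                       mentions$entity_class == "drug", , drop = FALSE]
    emen <- mentions[mentions$canonical_id == candidates$effect_id[r] &
                       mentions$entity_class == "effect", , drop = FALSE]
    if (!nrow(dmen) || !nrow(emen)) next
    for (u in intersect(unique(dmen$user_id), unique(emen$user_id))) {
      du <- dmen[dmen$user_id == u, , drop = FALSE]
      eu <- emen[emen$user_id == u, , drop = FALSE]
      grid <- expand.grid(i = seq_len(nrow(du)), j = seq_len(nrow(eu)))
      gap <- abs(as.numeric(du$date[grid$i] - eu$date[grid$j]))
      ok <- which(gap <= t_window)
      if (!length(ok)) next
      best <- ok[which.min(gap[ok])]
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = candidates$drug_id[r], effect_id = candidates$effect_id[r],
        user_id = u, drug_tweet_id = du$tweet_id[grid$i[best]],
        effect_tweet_id = eu$tweet_id[grid$j[best]], day_gap = gap[best],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
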