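#' Extract per-user entity timelines from a tweet corpus
#'
#' Runs [extract_entities()] over the corpus and groups the mentions by user
#' into chronologically ordered histories. Mention dates are the tweet dates
#' (timestamps truncated to day resolution).
#'
#' @param tweets Data frame from [read_tweets()] (columns `tweet_id`,
#'   `user_id`, `date`, `text`).
#' @param lex A [lexicon()].
#' @return Named list (by user id) of data frames with columns `user_id`,
#'   `tweet_id`, `date`, `canonical_id`, `entity_class`, sorted by date.
#' @export
extract_user_histories <- function(tweets, lex) {
  stopifnot(all(c("tweet_id", "user_id", "date", "text") %in% names(tweets)))
  mentions <- extract_entities(tweets, lex)
  if (!nrow(mentions)) return(stats::setNames(list(), character(0)))
  idx <- match(mentions$tweet_id, tweets$tweet_id)
  mentions$user_id <- tweets$user_id[idx]
  mentions$date <- tweets$date[idx]
  mentions <- mentions[order(mentions$user_id, mentions$date, mentions$tweet_id), ]
  cols <- c("user_id", "tweet_id", "date", "canonical_id", "entity_class")
  split(mentions[, cols], mentions$user_id)
}

#' Build one user's drug-effect graph
#'
#' An edge is drawn between a drug and an effect mentioned in the user's
#' history whenever the absolute calendar-day difference of some mention pair
#' is at most `t_window`. The edge's `temporal_weight` is the mean absolute
#' day difference over *all* qualifying mention pairs of that (drug, effect).
#' Temporal distance is direction-agnostic (the drug need not precede the
#' effect) and a same-tweet co-mention has distance 0. Nodes appear only if
#' they participate in at least one edge.
#'
#' @param history One element of [extract_user_histories()].
#' @param t_window Window length in days (default 20, must be >= 1).
#' @return A [deg] with `temporal_weight` on every edge.
#' @export
build_user_deg <- function(history, t_window = 20L) {
  stopifnot(is.data.frame(history), t_window >= 1)
  d <- history[history$entity_class == "drug", , drop = FALSE]
  e <- history[history$entity_class == "effect", , drop = FALSE]
  if (!nrow(d) || !nrow(e)) return(deg())
  grid <- expand.grid(i = seq_len(nrow(d)), j = seq_len(nrow(e)))
  gap <- abs(as.numeric(d$date[grid$i] - e$date[grid$j]))
  keep <- gap <= t_window
  if (!any(keep)) return(deg())
  key <- pair_key(d$canonical_id[grid$i][keep], e$canonical_id[grid$j][keep])
  w <- tapply(gap[keep], key, mean)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(
    drug_id = vapply(parts, `[[`, "", 1L),
    effect_id = vapply(parts, `[[`, "", 2L),
    label = "unlabeled",
    temporal_weight = as.numeric(w),
    frequency_weight = NA_real_,
    stringsAsFactors = FALSE
  )
  deg(drugs = unique(edges$drug_id), effects = unique(edges$effect_id),
      edges = edges)
}

#' Build all per-user graphs
#'
#' @inheritParams build_user_deg
#' @param user_histories List from [extract_user_histories()].
#' @param drop_empty Drop users whose history yields no edge (default `TRUE`).
#' @return Named list of [deg] objects.
#' @export
build_user_degs <- function(user_histories, t_window = 20L, drop_empty = TRUE) {
  degs <- lapply(user_histories, build_user_deg, t_window = t_window)
  if (drop_empty) degs <- degs[vapply(degs, function(g) nrow(g$edges) > 0L, TRUE)]
  degs
}

#' Build the Twitter-side drug-effect graph
#'
#' Builds one DEG per user with [build_user_deg()], merges them with
#' [merge_degs()] (temporal weights averaged over contributing users,
#' `frequency_weight` = number of contributing user graphs) and, when a
#' reference graph is given, labels each merged edge `"adverse"` if present
#' among the reference's adverse edges and `"pseudo_non_adverse"` otherwise.
#'
#' @inheritParams build_user_degs
#' @param sider_deg Optional reference [deg] (e.g. from [load_sider()]) used
#'   for labeling.
#' @return A [deg]; the attribute `"n_user_graphs"` records how many user
#'   graphs (with at least one edge) contributed.
#' @export
build_twitter_deg <- function(user_histories, sider_deg = NULL, t_window = 20L) {
  degs <- build_user_degs(user_histories, t_window = t_window)
  merged <- merge_degs(unname(degs))
  if (!is.null(sider_deg)) merged <- label_edges(merged, sider_deg)
  attr(merged, "n_user_graphs") <- length(degs)
  merged
}

#' Sweep the temporal window parameter
#'
#' Rebuilds the Twitter DEG for each window length and tabulates edge counts.
#' Total edges are non-decreasing in `t` (larger windows admit supersets of
#' qualifying mention pairs).
#'
#' @inheritParams build_twitter_deg
#' @param t_values Positive integer window lengths.
#' @return Data frame with columns `t`, `total_edges`, `adverse_edges`,
#'   `pct_adverse` (0 when there are no edges).
#' @export
window_sweep <- function(user_histories, sider_deg, t_values) {
  stopifnot(all(t_values >= 1))
  rows <- lapply(t_values, function(t) {
    g <- build_twitter_deg(user_histories, sider_deg, t_window = t)
    total <- nrow(g$edges)
    adverse <- sum(g$edges$label == "adverse")
    data.frame(t = t, total_edges = total, adverse_edges = adverse,
               pct_adverse = if (total) adverse / total else 0)
  })
  do.call(rbind, rows)
}
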