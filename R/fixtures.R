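#' Generate a planted-block SIDER-like drug-effect graph
#'
#' Drugs and effects are partitioned into `n_blocks` pharmacological blocks
#' (contiguous, sizes differing by at most one). An adverse edge is drawn
#' independently for each (drug, effect) pair with probability `p_in` when the
#' two endpoints share a block and `p_out` otherwise. With `p_in > p_out` the
#' adverse edges are topologically distinguishable from sampled
#' pseudo-negatives; with `p_in = p_out` there is no signal by construction.
#' Byte-identical reruns from the same `seed`.
#'
#' @param n_drugs,n_effects Node counts (defaults 50 and 100).
#' @param n_blocks Number of planted blocks (default 5).
#' @param p_in,p_out Within-block and cross-block adverse edge probabilities
#'   (defaults 0.6 and 0.02; must satisfy `0 <= p_out <= p_in <= 1`).
#' @param seed Integer seed.
#' @return List with the [deg] (`deg`), and named integer vectors
#'   `drug_blocks`, `effect_blocks` (the ground-truth block map).
#' @export
generate_planted_sider <- function(n_drugs = 50L, n_effects = 100L,
                                   n_blocks = 5L, p_in = 0.6, p_out = 0.02,
                                   seed) {
  if (!(p_out >= 0 && p_in >= p_out && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  stopifnot(n_drugs >= 1L, n_effects >= 1L, n_blocks >= 1L)
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  effect_ids <- sprintf("E%03d", seq_len(n_effects))
  db <- sort(rep_len(seq_len(n_blocks), n_drugs))
  eb <- sort(rep_len(seq_len(n_blocks), n_effects))
  p <- ifelse(outer(db, eb, "=="), p_in, p_out)
  hit <- local_seed(seed, stats::runif(length(p)) < p)
  idx <- which(matrix(hit, nrow = n_drugs))
  di <- (idx - 1L) %% n_drugs + 1L
  ei <- (idx - 1L) %/% n_drugs + 1L
  edges <- data.frame(drug_id = drug_ids[di], effect_id = effect_ids[ei],
                      label = "adverse", stringsAsFactors = FALSE)
  g <- deg(drugs = data.frame(id = drug_ids, name = paste("Drug", drug_ids)),
           effects = data.frame(id = effect_ids, name = paste("Effect", effect_ids)),
           edges = edges)
  list(deg = g,
       drug_blocks = stats::setNames(db, drug_ids),
       effect_blocks = stats::setNames(eb, effect_ids))
}

stream_lexicon <- function(x) {
  drug_surfaces <- c(stats::setNames(x$drugs$id, tolower(x$drugs$id)),
                     stats::setNames(x$drugs$id, paste0("brand", tolower(x$drugs$id))))
  effect_surfaces <- c(stats::setNames(x$effects$id, tolower(x$effects$id)),
                       stats::setNames(x$effects$id,
                                       paste("sore", tolower(x$effects$id))))
  lexicon(drug_synonyms = drug_surfaces, effect_terms = effect_surfaces,
          stop_list = c("pic", "lol"))
}

#' Generate a synthetic tweet stream with a ground-truth edge ledger
#'
#' Emulates the per-user timelines that the Twitter-side graph builder
#' consumes. Each user is assigned a few planted (drug, effect) pairs from
#' `x`; for every pair the user posts a drug tweet and an effect tweet whose
#' calendar-day offset is sampled from `0:max_offset_days`. Pairs are placed
#' in time clusters separated by more than any usual window (60 days), so the
#' ledger records exactly the edges (and mean offsets) a window of at least
#' `max_offset_days` recovers. Experiential tweets carry pronouns, entity
#' surfaces, block-specific topic vocabulary and sentiment-bearing words;
#' spam tweets carry hashtag bursts and URLs but no entities. Lone spurious
#' entity mentions (isolated in their own cluster) exercise the
#' no-partner-within-window rule.
#'
#' @param x A [deg] supplying the drug and effect ids (e.g. from
#'   [generate_planted_sider()]).
#' @param n_users Number of users (default 30).
#' @param pairs_per_user Integer range (min, max) of planted pairs per user.
#' @param max_offset_days Largest drug-effect day offset (default 20).
#' @param adverse_fraction Probability a planted pair is drawn from the
#'   adverse edges of `x` rather than from random non-edges (default 0.7).
#' @param spurious_rate Probability a user gets one isolated lone-entity
#'   cluster (default 0.2).
#' @param spam_per_user Integer range of spam tweets per user.
#' @param pos_word_rate,neg_word_rate Sentiment word injection rates for drug
#'   and effect tweets respectively.
#' @param seed Integer seed.
#' @return List with `tweets` (data frame: `tweet_id`, `user_id`,
#'   `created_at`, `date`, `text`, `label` with 1 = experiential), `lexicon`
#'   (a [lexicon()] covering all surfaces) and `ledger` (data frame `user_id`,
#'   `drug_id`, `effect_id`, `offset_days`: every intended edge with its true
#'   offset).
#' @export
generate_tweet_stream <- function(x, n_users = 30L, pairs_per_user = c(1L, 3L),
                                  max_offset_days = 20L, adverse_fraction = 0.7,
                                  spurious_rate = 0.2, spam_per_user = c(1L, 3L),
                                  pos_word_rate = 0.3, neg_word_rate = 0.3,
                                  seed) {
  stopifnot(inherits(x, "deg"), max_offset_days >= 0L)
  for (r in c(adverse_fraction, spurious_rate, pos_word_rate, neg_word_rate)) {
    stopifnot(r >= 0, r <= 1)
  }
  lex <- stream_lexicon(x)
  base_date <- as.Date("2016-01-01")
  cluster_gap <- 60L
  adverse <- x$edges[x$edges$label == "adverse", , drop = FALSE]
  drug_block <- attr(x, "drug_blocks")
  topic_word_pool <- function(drug_id) {
    b <- if (!is.null(drug_block) && drug_id %in% names(drug_block)) {
      drug_block[[drug_id]]
    } else {
      (utf8ToInt(substr(drug_id, nchar(drug_id), nchar(drug_id))) %% 5L) + 1L
    }
    paste0("topic", b, letters[1:6])
  }
  pos_words <- default_positive_words()
  neg_words <- default_negative_words()
  local_seed(seed, {
    tweets <- list()
    ledger <- list()
    tid <- 0L
    next_tweet <- function(user, day, text, label) {
      tid <<- tid + 1L
      date <- base_date + day
      tweets[[tid]] <<- data.frame(
        tweet_id = sprintf("t%05d", tid), user_id = user,
        created_at = paste0(format(date), "T12:00:00Z"), date = date,
        text = text, label = label, stringsAsFactors = FALSE)
    }
    if (n_users > 0L) {
      for (u in seq_len(n_users)) {
        user <- sprintf("u%03d", u)
        n_pairs <- sample(seq(pairs_per_user[1L], pairs_per_user[2L]), 1L)
        picked <- character(0)
        cluster <- 0L
        for (p in seq_len(n_pairs)) {
          from_adverse <- nrow(adverse) > 0L && stats::runif(1) < adverse_fraction
          for (try in 1:20) {
            if (from_adverse) {
              row <- adverse[sample.int(nrow(adverse), 1L), ]
              pair <- c(row$drug_id, row$effect_id)
            } else {
              pair <- c(sample(x$drugs$id, 1L), sample(x$effects$id, 1L))
            }
            if (!pair_key(pair[1L], pair[2L]) %in% picked) break
          }
          key <- pair_key(pair[1L], pair[2L])
          if (key %in% picked) next
          picked <- c(picked, key)
          base_day <- cluster * cluster_gap
          cluster <- cluster + 1L
          offset <- sample.int(max_offset_days + 1L, 1L) - 1L
          tw <- sample(topic_word_pool(pair[1L]), 2L)
          dtext <- sprintf("i took %s today %s %s", tolower(pair[1L]),
                           tw[1L], tw[2L])
          if (stats::runif(1) < pos_word_rate) {
            dtext <- paste(dtext, sample(pos_words, 1L))
          }
          etext <- sprintf("my %s is acting up again %s", tolower(pair[2L]),
                           tw[1L])
          if (stats::runif(1) < neg_word_rate) {
            etext <- paste(etext, sample(neg_words, 1L))
          }
          if (stats::runif(1) < 0.1) dtext <- paste(dtext, "http://pics.example.com/x")
          next_tweet(user, base_day, dtext, 1L)
          next_tweet(user, base_day + offset, etext, 1L)
          ledger[[length(ledger) + 1L]] <- data.frame(
            user_id = user, drug_id = pair[1L], effect_id = pair[2L],
            offset_days = offset, stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < spurious_rate) {
          lone_day <- cluster * cluster_gap
          if (stats::runif(1) < 0.5) {
            ent <- tolower(sample(x$drugs$id, 1L))
            next_tweet(user, lone_day, sprintf("i refilled my %s just in case", ent), 1L)
          } else {
            ent <- tolower(sample(x$effects$id, 1L))
            next_tweet(user, lone_day, sprintf("remember that %s i had last year", ent), 1L)
          }
        }
        n_spam <- sample(seq(spam_per_user[1L], spam_per_user[2L]), 1L)
        for (s in seq_len(n_spam)) {
          stext <- "amazing deals #win #free #click now http://spam.example.com/offer"
          if (stats::runif(1) < 0.1) stext <- paste(stext, "you")
          next_tweet(user, sample.int(cluster_gap * (cluster + 1L), 1L) - 1L, stext, 0L)
        }
      }
    }
    tweets <- if (length(tweets)) do.call(rbind, tweets) else
      data.frame(tweet_id = character(), user_id = character(),
                 created_at = character(), date = as.Date(character()),
                 text = character(), label = integer(), stringsAsFactors = FALSE)
    ledger <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(user_id = character(), drug_id = character(),
                 effect_id = character(), offset_days = numeric(),
                 stringsAsFactors = FALSE)
    list(tweets = tweets, lexicon = lex, ledger = ledger)
  })
}

#' Expected merged edges implied by a stream ledger
#'
#' Aggregates a [generate_tweet_stream()] ledger to the merged-graph
#' expectation: per (drug, effect) pair, the mean offset over contributing
#' users (`temporal_weight`) and the user count (`frequency_weight`).
#'
#' @param ledger The `ledger` component of [generate_tweet_stream()].
#' @return Data frame `drug_id`, `effect_id`, `temporal_weight`,
#'   `frequency_weight`.
#' @export
ledger_expected_edges <- function(ledger) {
  key <- pair_key(ledger$drug_id, ledger$effect_id)
  w <- tapply(ledger$offset_days, key, mean)
  cnt <- tapply(rep(1L, nrow(ledger)), key, sum)
  first <- !duplicated(key)
  out <- data.frame(drug_id = ledger$drug_id[first],
                    effect_id = ledger$effect_id[first],
                    stringsAsFactors = FALSE)
  k <- pair_key(out$drug_id, out$effect_id)
  out$temporal_weight <- as.numeric(w[k])
  out$frequency_weight <- as.numeric(cnt[k])
  out
}

#' The 18-tweet / 9-user worked example
#'
#' A small, permanently fixed corpus illustrating the Twitter-side
#' construction: 18 tweets from 9 users (User 1 posts 3 tweets, User 5 posts
#' one, the rest two each). User 1 mentions Clonazepam on 2016-02-09 and
#' Depression, Pain and Confusional State on 2016-02-11, so their graph has 4
#' nodes and 3 edges of temporal weight 2. Across all users exactly three
#' drugs (Clonazepam, Prednisone, Xanax) and nine effects are mentioned, every
#' merged edge coming from a single user (all frequency weights 1). Canonical
#' ids are synthetic stand-ins styled after PubChem CIDs and UMLS CUIs; the
#' bundled SIDER-style table is likewise a synthetic stand-in used only to
#' label the example's edges.
#'
#' @return List with `tweets` (18-row data frame), `lexicon`, `sider` (a small
#'   SIDER-style relationship data frame for [load_sider()]) and `expected`
#'   (the printed counts: users, drugs, effects, edges, and the User 1
#'   subgraph shape).
#' @export
case_study_fixture <- function() {
  lex <- lexicon(
    drug_synonyms = c(
      "clonazepam" = "CID2802", "klonopin" = "CID2802",
      "prednisone" = "CID5865",
      "xanax" = "CID2118", "alprazolam" = "CID2118"),
    effect_terms = c(
      "depression" = "C0011570", "depressed" = "C0011570",
      "pain" = "C0030193",
      "confusional state" = "C0009676", "confused" = "C0009676",
      "anxiety" = "C0003467", "anxious" = "C0003467",
      "exhaustion" = "C0015672", "exhausted" = "C0015672",
      "malnutrition" = "C0162429",
      "nightmares" = "C0028084", "nightmare" = "C0028084",
      "hunger" = "C0020175",
      "tremors" = "C0040822", "tremor" = "C0040822"),
    stop_list = "pic")
  tw <- function(id, user, date, text) {
    data.frame(tweet_id = id, user_id = user,
               created_at = paste0(date, "T12:00:00Z"),
               date = as.Date(date), text = text, stringsAsFactors = FALSE)
  }
  tweets <- rbind(
    tw("t01", "user1", "2016-02-09", "took my clonazepam before bed tonight"),
    tw("t02", "user1", "2016-02-11", "my depression is worse and this pain will not quit"),
    tw("t03", "user1", "2016-02-11", "been in a confusional state all day"),
    tw("t04", "user2", "2016-02-01", "prednisone did kill most of my gut microbes"),
    tw("t05", "user2", "2016-02-03", "and it worsened my malnutrition though"),
    tw("t06", "user3", "2016-02-02", "starting xanax again this week"),
    tw("t07", "user3", "2016-02-04", "my anxiety is still through the roof"),
    tw("t08", "user4", "2016-02-05", "another round of prednisone for me"),
    tw("t09", "user4", "2016-02-06", "the exhaustion is unreal today"),
    tw("t10", "user5", "2016-02-07", "xanax gives me nightmares every single night"),
    tw("t11", "user6", "2016-02-03", "doctor upped my clonazepam dose"),
    tw("t12", "user6", "2016-02-08", "the hunger never stops lately"),
    tw("t13", "user7", "2016-02-02", "prednisone taper starts tomorrow"),
    tw("t14", "user7", "2016-02-09", "hands shaking with tremors again"),
    tw("t15", "user8", "2016-02-04", "took a xanax before the flight"),
    tw("t16", "user8", "2016-02-10", "so exhausted i cannot move"),
    tw("t17", "user9", "2016-02-05", "back on clonazepam as of today"),
    tw("t18", "user9", "2016-02-12", "feeling anxious about everything")
  )
  sider <- data.frame(
    drug_id = c("CID2802", "CID2802", "CID2802", "CID5865", "CID5865",
                 "CID2118", "CID2118"),
    drug_name = c("Clonazepam", "Clonazepam", "Clonazepam", "Prednisone",
                  "Prednisone", "Alprazolam", "Alprazolam"),
    effect_id = c("C0011570", "C0009676", "C0015672", "C0162429", "C0015672",
                   "C0003467", "C0028084"),
    effect_name = c("Depression", "Confusional state", "Exhaustion",
                    "Malnutrition", "Exhaustion", "Anxiety", "Nightmares"),
    stringsAsFactors = FALSE)
  list(
    tweets = tweets,
    lexicon = lex,
    sider = sider,
    expected = list(
      n_users = 9L, n_drugs = 3L, n_effects = 9L, n_edges = 11L,
      frequency_weight = 1,
      user1 = list(user_id = "user1", n_nodes = 4L, n_edges = 3L,
                   temporal_weight = 2)
    )
  )
}
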