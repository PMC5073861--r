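#' Default word lists for tweet filtering
#'
#' Negation and pronoun counts in the tweet filter use configurable word
#' lists; these are the shipped defaults.
#'
#' @return Character vector of lowercase words.
#' @export
default_negation_words <- function() {
  c("no", "not", "never", "n't", "without", "cannot")
}

#' @rdname default_negation_words
#' @export
default_pronoun_words <- function() {
  c("i", "me", "my", "mine", "we", "us", "our", "you", "your",
    "he", "she", "him", "her", "they", "them")
}

url_pattern <- paste0(
  "(https?://[^[:space:]]+",
  "|www\\.[^[:space:]]+",
  "|\\b[[:alnum:]][[:alnum:].-]*\\.(com|net|org|co|io|gov|edu|ly)(/[^[:space:]]*)?)"
)

# Blank out regex matches with spaces of equal length so character spans keep
# their coordinates in the original text.
blank_matches <- function(text, pattern, keep_first_char = FALSE) {
  m <- gregexpr(pattern, text, ignore.case = TRUE, perl = TRUE)[[1L]]
  n <- if (m[1L] == -1L) 0L else length(m)
  if (n > 0L) {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    for (i in seq_len(n)) {
      from <- m[i] + if (keep_first_char) 1L else 0L
      to <- m[i] + attr(m, "match.length")[i] - 1L
      if (from <= to) chars[from:to] <- " "
    }
    text <- paste(chars, collapse = "")
  }
  list(text = text, n = n)
}

# Full text analysis: URL and @-handle removal (after counting), hashtag
# unwrapping (the '#' is dropped, the word part kept), then lowercase tokens
# split on non-alphanumeric boundaries, with character offsets.
analyze_text <- function(text) {
  if (is.na(text)) text <- ""
  urls <- blank_matches(text, url_pattern)
  handles <- blank_matches(urls$text, "@[[:alnum:]_]+")
  m <- gregexpr("#[[:alnum:]_]", handles$text)[[1L]]
  n_hashtags <- if (m[1L] == -1L) 0L else length(m)
  cleaned <- gsub("#", " ", handles$text, fixed = TRUE)
  low <- tolower(cleaned)
  tm <- gregexpr("[[:alnum:]]+", low)[[1L]]
  if (tm[1L] == -1L) {
    tokens <- character(0)
    starts <- integer(0)
    ends <- integer(0)
  } else {
    starts <- as.integer(tm)
    ends <- starts + attr(tm, "match.length")
    tokens <- substring(low, starts, ends - 1L)
  }
  list(tokens = tokens, starts = starts, ends = ends,
       n_urls = urls$n, n_hashtags = n_hashtags, text = text)
}

#' Tokenize tweet text
#'
#' Lowercases and splits on non-alphanumeric boundaries. URLs and `@`-handles
#' are removed (they are counted separately by [tweet_filter_features()]);
#' hashtag tokens retain their word part.
#'
#' @param text A character string.
#' @return Character vector of tokens.
#' @examples
#' tokenize("I love Advil! I no longer have a headache!")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  analyze_text(text)$tokens
}

normalize_surface <- function(x) {
  vapply(x, function(s) paste(analyze_text(s)$tokens, collapse = " "), "",
         USE.NAMES = FALSE)
}

as_term_map <- function(x, what) {
  if (is.null(x)) return(stats::setNames(character(0), character(0)))
  if (is.data.frame(x)) {
    stopifnot(all(c("surface", "canonical_id") %in% names(x)))
    x <- stats::setNames(as.character(x$canonical_id), as.character(x$surface))
  }
  if (is.null(names(x))) stop(what, " must map surface forms to ids", call. = FALSE)
  stats::setNames(as.character(x), normalize_surface(names(x)))
}

#' Build an entity lexicon
#'
#' Maps lowercase surface forms (up to 5 tokens) to canonical drug or effect
#' ids, resolving synonyms and trade names to one identifier. Stop-listed
#' surfaces (Twitter-ambiguous abbreviations such as "pic") never yield
#' mentions. Lookups are case-insensitive.
#'
#' @param drug_synonyms,effect_terms Data frame with columns `surface`,
#'   `canonical_id`, or a named character vector (names = surfaces, values =
#'   ids).
#' @param stop_list Character vector of suppressed surface forms.
#' @return An object of class `"deg_lexicon"`.
#' @export
lexicon <- function(drug_synonyms = NULL, effect_terms = NULL, stop_list = character()) {
  structure(list(
    drug_synonyms = as_term_map(drug_synonyms, "drug_synonyms"),
    effect_terms = as_term_map(effect_terms, "effect_terms"),
    stop_list = normalize_surface(as.character(stop_list))
  ), class = "deg_lexicon")
}

#' @export
print.deg_lexicon <- function(x, ...) {
  cat(sprintf("<deg_lexicon> %d drug surfaces, %d effect surfaces, %d stop terms\n",
              length(x$drug_synonyms), length(x$effect_terms), length(x$stop_list)))
  invisible(x)
}

#' Read / write lexicon files
#'
#' Per-class TSV files with columns `surface` and `canonical_id` (header row);
#' the stop list holds one term per line.
#'
#' @param drug_path,effect_path Paths to the synonym tables.
#' @param stop_path Optional stop-list path.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(drug_path, effect_path, stop_path = NULL) {
  read_tsv <- function(p) utils::read.delim(p, colClasses = "character",
                                            quote = "", fileEncoding = "UTF-8")
  stop_list <- if (!is.null(stop_path)) readLines(stop_path, encoding = "UTF-8") else character()
  lexicon(read_tsv(drug_path), read_tsv(effect_path),
          stop_list[nzchar(stop_list)])
}

#' @rdname read_lexicon
#' @param lex A [lexicon()].
#' @param dir Output directory; files `drug_synonyms.tsv`, `effect_terms.tsv`,
#'   `stop_list.txt` are written there.
#' @export
write_lexicon <- function(lex, dir) {
  stopifnot(inherits(lex, "deg_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_map <- function(map, path) {
    utils::write.table(
      data.frame(surface = names(map), canonical_id = unname(map)),
      path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_map(lex$drug_synonyms, file.path(dir, "drug_synonyms.tsv"))
  write_map(lex$effect_terms, file.path(dir, "effect_terms.tsv"))
  writeLines(lex$stop_list, file.path(dir, "stop_list.txt"))
  invisible(dir)
}

max_ngram <- 5L

#' Extract drug and effect mentions from tweets
#'
#' Dictionary-based extractor: a greedy longest-match, case-insensitive scan
#' over token n-grams (n up to 5). Stop-listed surfaces are suppressed;
#' surviving matches are canonicalized through the lexicon. Repeated mentions
#' of the same canonical id within one tweet collapse to a single mention.
#'
#' @param tweets A data frame of tweets with columns `tweet_id` and `text`
#'   (a single tweet as a one-row data frame or named list also works).
#' @param lex A [lexicon()].
#' @return Data frame with one row per mention: `tweet_id`, `canonical_id`,
#'   `entity_class` (`"drug"` or `"effect"`), `surface` (matched text) and the
#'   half-open character span `start`, `end` in the tweet text.
#' @export
extract_entities <- function(tweets, lex) {
  stopifnot(inherits(lex, "deg_lexicon"))
  if (!is.data.frame(tweets)) tweets <- as.data.frame(tweets, stringsAsFactors = FALSE)
  stopifnot(all(c("tweet_id", "text") %in% names(tweets)))
  empty <- data.frame(tweet_id = character(), canonical_id = character(),
                      entity_class = character(), surface = character(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
  if (!nrow(tweets)) return(empty)
  out <- vector("list", nrow(tweets))
  for (r in seq_len(nrow(tweets))) {
    out[[r]] <- extract_entities_one(tweets$tweet_id[r], tweets$text[r], lex)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

extract_entities_one <- function(tweet_id, text, lex) {
  an <- analyze_text(text)
  toks <- an$tokens
  n <- length(toks)
  rows <- list()
  i <- 1L
  while (i <= n) {
    consumed <- 1L
    for (g in seq(min(max_ngram, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + g - 1L)], collapse = " ")
      if (key %in% lex$stop_list) {
        consumed <- g
        break
      }
      cls <- if (key %in% names(lex$drug_synonyms)) "drug"
             else if (key %in% names(lex$effect_terms)) "effect"
             else NA_character_
      if (!is.na(cls)) {
        map <- if (cls == "drug") lex$drug_synonyms else lex$effect_terms
        start <- an$starts[i]
        end <- an$ends[i + g - 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          tweet_id = tweet_id,
          canonical_id = unname(map[[key]]),
          entity_class = cls,
          surface = substring(text, start, end - 1L),
          start = start, end = end, stringsAsFactors = FALSE)
        consumed <- g
        break
      }
    }
    i <- i + consumed
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  res[!duplicated(res$canonical_id), , drop = FALSE]
}

#' Fit a bag-of-words vocabulary
#'
#' Vocabulary terms are training-corpus tokens with document frequency at
#' least `min_df` (default 2).
#'
#' @param texts Character vector of training texts.
#' @param min_df Minimum number of documents a term must appear in.
#' @return Sorted character vector of vocabulary terms.
#' @export
fit_vocabulary <- function(texts, min_df = 2L) {
  df <- table(unlist(lapply(texts, function(t) unique(analyze_text(t)$tokens))))
  sort(names(df)[df >= min_df])
}

#' Text features for experiential-tweet classification
#'
#' Seven feature families: number of hashtags, negation words, URLs, pronouns,
#' drug entities and effect entities, plus a bag-of-words term-frequency block
#' over a fitted vocabulary. URL and hashtag counts are taken before the
#' corresponding substrings are stripped by tokenization.
#'
#' @param tweets Data frame with columns `tweet_id`, `text`.
#' @param lex A [lexicon()] used for the entity counts.
#' @param vocabulary Vocabulary from [fit_vocabulary()]; `NULL` omits the
#'   bag-of-words block.
#' @param negation_words,pronoun_words Word lists; see
#'   [default_negation_words()].
#' @return Numeric matrix, one row per tweet; columns `n_hashtags`,
#'   `n_negations`, `n_urls`, `n_pronouns`, `n_drug_entities`,
#'   `n_effect_entities`, then `bow_<term>` columns.
#' @export
tweet_filter_features <- function(tweets, lex, vocabulary = NULL,
                                  negation_words = default_negation_words(),
                                  pronoun_words = default_pronoun_words()) {
  stopifnot(inherits(lex, "deg_lexicon"))
  n <- nrow(tweets)
  scalar_cols <- c("n_hashtags", "n_negations", "n_urls", "n_pronouns",
                   "n_drug_entities", "n_effect_entities")
  bow_cols <- if (length(vocabulary)) paste0("bow_", vocabulary) else character(0)
  out <- matrix(0, nrow = n, ncol = length(scalar_cols) + length(bow_cols),
                dimnames = list(NULL, c(scalar_cols, bow_cols)))
  count_nt <- "n't" %in% negation_words
  for (r in seq_len(n)) {
    an <- analyze_text(tweets$text[r])
    toks <- an$tokens
    negs <- sum(toks %in% negation_words)
    if (count_nt) {
      m <- gregexpr("n['’]t", tolower(tweets$text[r]))[[1L]]
      if (m[1L] != -1L) negs <- negs + length(m)
    }
    men <- extract_entities_one(tweets$tweet_id[r], tweets$text[r], lex)
    out[r, "n_hashtags"] <- an$n_hashtags
    out[r, "n_negations"] <- negs
    out[r, "n_urls"] <- an$n_urls
    out[r, "n_pronouns"] <- sum(toks %in% pronoun_words)
    if (!is.null(men)) {
      out[r, "n_drug_entities"] <- sum(men$entity_class == "drug")
      out[r, "n_effect_entities"] <- sum(men$entity_class == "effect")
    }
    if (length(vocabulary)) {
      tf <- table(toks[toks %in% vocabulary])
      if (length(tf)) out[r, paste0("bow_", names(tf))] <- as.numeric(tf)
    }
  }
  out
}

#' Train the experiential-tweet filter
#'
#' Labels tweets experiential (personal experience) versus non-experiential
#' (spam, news, advertisements) with a 10-tree random forest over the
#' [tweet_filter_features()] representation. The labeled corpus is split into
#' a training and a held-out fraction; the vocabulary is fitted on the
#' training split only. 10-fold cross-validated and held-out precision,
#' recall and F1 are reported. Fully reproducible from `seed`.
#'
#' @param tweets Data frame with columns `tweet_id`, `text` and integer
#'   `label` (1 = experiential, 0 = non-experiential).
#' @param lex A [lexicon()].
#' @param split_fraction Training fraction (default 0.6).
#' @param seed Integer seed.
#' @param n_trees Ensemble size (default 10).
#' @param folds Cross-validation folds on the training split (default 10).
#' @param min_df Vocabulary document-frequency cutoff.
#' @inheritParams tweet_filter_features
#' @return An object of class `"experiential_filter"`: the fitted model plus
#'   `cv` (per-metric mean and sd over folds) and `test` (held-out precision,
#'   recall, f1).
#' @export
train_experiential_filter <- function(tweets, lex, split_fraction = 0.6, seed,
                                      n_trees = 10L, folds = 10L, min_df = 2L,
                                      negation_words = default_negation_words(),
                                      pronoun_words = default_pronoun_words()) {
  stopifnot(is.data.frame(tweets), "label" %in% names(tweets))
  stopifnot(split_fraction > 0, split_fraction < 1)
  y_all <- as.integer(tweets$label)
  if (length(unique(y_all)) < 2L) {
    stop("both classes (experiential and non-experiential) must be present",
         call. = FALSE)
  }
  local_seed(seed, {
    n <- nrow(tweets)
    train_idx <- sort(sample.int(n, round(split_fraction * n)))
    test_idx <- setdiff(seq_len(n), train_idx)
    vocabulary <- fit_vocabulary(tweets$text[train_idx], min_df = min_df)
    feats <- tweet_filter_features(tweets, lex, vocabulary,
                                   negation_words, pronoun_words)
    y <- factor(y_all, levels = c(0L, 1L))
    cv <- cv_metrics(feats[train_idx, , drop = FALSE], y[train_idx],
                     folds = folds, n_trees = n_trees, positive = "1")
    model <- randomForest::randomForest(x = feats[train_idx, , drop = FALSE],
                                        y = y[train_idx], ntree = n_trees)
    pred <- stats::predict(model, feats[test_idx, , drop = FALSE])
    test <- evaluate_predictions(pred, y[test_idx], positive = "1")
    structure(list(model = model, vocabulary = vocabulary,
                   negation_words = negation_words,
                   pronoun_words = pronoun_words,
                   n_trees = n_trees, cv = cv, test = test),
              class = "experiential_filter")
  })
}

#' @export
print.experiential_filter <- function(x, ...) {
  cat(sprintf("<experiential_filter> %d trees, %d vocabulary terms\n",
              x$n_trees, length(x$vocabulary)))
  cat(sprintf("  held-out: precision %.3f, recall %.3f, f1 %.3f\n",
              x$test["precision"], x$test["recall"], x$test["f1"]))
  invisible(x)
}

#' Keep only tweets predicted experiential
#'
#' Applies a trained [train_experiential_filter()] model; input order is
#' preserved and the output is a subset of the input.
#'
#' @param filter An `"experiential_filter"`.
#' @param tweets Data frame with columns `tweet_id`, `text`.
#' @param lex The [lexicon()] used at training time.
#' @return The rows of `tweets` predicted experiential.
#' @export
apply_filter <- function(filter, tweets, lex) {
  stopifnot(inherits(filter, "experiential_filter"))
  if (is.null(filter$vocabulary)) {
    stop("filter carries no vocabulary; cannot reproduce training features",
         call. = FALSE)
  }
  if (!nrow(tweets)) return(tweets)
  feats <- tweet_filter_features(tweets, lex, filter$vocabulary,
                                 filter$negation_words, filter$pronoun_words)
  pred <- stats::predict(filter$model, feats)
  tweets[pred == "1", , drop = FALSE]
}

#' Read / write tweets as JSON-lines
#'
#' One JSON object per line with fields `id`, `user_id`, `created_at`
#' (ISO-8601) and `text`; an optional integer `label` field (1 = experiential)
#' is carried through when present.
#'
#' @param path File path.
#' @return `read_tweets` returns a data frame with columns `tweet_id`,
#'   `user_id`, `created_at`, `date` (class `Date`), `text` and possibly
#'   `label`.
#' @export
read_tweets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  get_chr <- function(f) vapply(recs, function(r) as.character(r[[f]] %||% NA_character_), "")
  out <- data.frame(tweet_id = get_chr("id"), user_id = get_chr("user_id"),
                    created_at = get_chr("created_at"), text = get_chr("text"),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$tweet_id) | !nzchar(out$tweet_id))) {
    stop("tweet with missing id", call. = FALSE)
  }
  out$date <- as.Date(strptime(substr(out$created_at, 1L, 10L), "%Y-%m-%d"))
  if (anyNA(out$date)) {
    stop("unparseable created_at timestamp at line ",
         which(is.na(out$date))[1L], call. = FALSE)
  }
  if (all(vapply(recs, function(r) !is.null(r$label), TRUE))) {
    out$label <- vapply(recs, function(r) as.integer(r$label), 1L)
  }
  out[, c("tweet_id", "user_id", "created_at", "date", "text",
          intersect("label", names(out)))]
}

#' @rdname read_tweets
#' @param tweets Data frame with columns `tweet_id`, `user_id`, `created_at`,
#'   `text` and optionally `label`.
#' @export
write_tweets <- function(tweets, path) {
  rows <- vapply(seq_len(nrow(tweets)), function(r) {
    rec <- list(id = tweets$tweet_id[r], user_id = tweets$user_id[r],
                created_at = tweets$created_at[r], text = tweets$text[r])
    if ("label" %in% names(tweets)) rec$label <- as.integer(tweets$label[r])
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, "")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
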