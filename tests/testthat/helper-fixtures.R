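# Toy graph T1: drugs d1, d2; effects e1, e2, e3;
# edges d1-e1, d1-e2, d2-e2, d2-e3.
toy_t1 <- function() {
  deg(drugs = c("d1", "d2"), effects = c("e1", "e2", "e3"),
      edges = data.frame(drug_id = c("d1", "d1", "d2", "d2"),
                         effect_id = c("e1", "e2", "e2", "e3")))
}

# T1 with the extra edge d1-e3 actually inserted.
toy_t1_plus <- function() {
  deg(drugs = c("d1", "d2"), effects = c("e1", "e2", "e3"),
      edges = data.frame(drug_id = c("d1", "d1", "d1", "d2", "d2"),
                         effect_id = c("e1", "e2", "e3", "e2", "e3")))
}

# Minimal drug/effect lexicon used across pipeline tests.
tiny_lexicon <- function() {
  lexicon(
    drug_synonyms = c("advil" = "ibuprofen", "motrin" = "ibuprofen",
                      "prednisone" = "prednisone",
                      "pravastatin" = "pravastatin"),
    effect_terms = c("headache" = "headache", "malnutrition" = "malnutrition",
                     "eczema" = "eczema", "sore throat" = "sore_throat"),
    stop_list = "pic")
}

make_tweets <- function(texts, user_id = "u1",
                        dates = rep("2016-02-01", length(texts))) {
  data.frame(tweet_id = sprintf("tw%03d", seq_along(texts)),
             user_id = user_id,
             created_at = paste0(dates, "T09:00:00Z"),
             date = as.Date(dates), text = texts, stringsAsFactors = FALSE)
}

# Small perfectly separable labeled corpus: experiential tweets carry
# pronouns and drug mentions; spam carries >= 3 hashtags and a URL.
separable_corpus <- function(n_each = 30L) {
  exp_texts <- sprintf("i took advil and my headache is gone day %d", seq_len(n_each))
  spam_texts <- sprintf("deal %d #win #free #click buy now http://spam.example.com", seq_len(n_each))
  out <- make_tweets(c(exp_texts, spam_texts),
                     user_id = rep(c("ue", "us"), each = n_each))
  out$label <- rep(c(1L, 0L), each = n_each)
  out
}
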