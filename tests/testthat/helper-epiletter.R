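# English-mirror preprocessing config so retention-rule tests read like
# the worked examples they encode.
english_pp <- function(whitelist_bigrams = character(), ...) {
  preprocess_config(
    stopwords = c("no", "not", "never", "without", "the", "a", "an", "her",
                  "his", "she", "he", "of", "and", "was", "is", "fever"),
    negations = c("no", "not", "never", "without"),
    whitelist_bigrams = whitelist_bigrams,
    pronouns = c("her", "his", "she", "he"),
    keep_pronoun_with = c("mouth", "arm", "eyes"),
    ...)
}

# Corpus comparison helper: field-for-field tibble equality, ignoring
# the provenance tag (which records where a corpus came from).
plain_corpus <- function(x) {
  out <- tibble::as_tibble(x)
  attr(out, "provenance") <- NULL
  out
}

# Minimal valid letters for corpus-level tests.
make_letters <- function(texts,
                         final = rep("epilepsy", length(texts)),
                         initial = final,
                         site = rep("site_A", length(texts)),
                         ids = sprintf("T%03d", seq_along(texts))) {
  as_letter_corpus(tibble::tibble(
    id = ids, site = site, anamnesis_text = texts,
    sex = rep(c("male", "female"), length.out = length(texts)),
    age_years = seq_along(texts) + 0.5,
    initial_dx = initial, final_dx = final), provenance = "test fixture")
}

# Short-letter synthetic configuration: the default class structure and
# lexicons but 30-150 word letters, for fast distributional tests.
small_cfg <- function(n = 400, seed = 7L, ...) {
  synth_config(n_letters = n,
               length_model = list(min_words = 30L, max_words = 150L,
                                   median_target = 60, mean_target = 63),
               seed = seed, ...)
}

# Independent brute-force Bayes enumeration for tiny Naive Bayes
# problems: direct products of smoothed probabilities, no logs, no
# shared code with fit_nb()/predict().
brute_nb_posteriors <- function(W_train, labels, alpha, W_test) {
  classes <- c("epilepsy", "no_epilepsy")
  V <- ncol(W_train)
  phat <- vapply(classes, function(cl) {
    s <- colSums(W_train[labels == cl, , drop = FALSE])
    (s + alpha) / (sum(s) + alpha * V)
  }, numeric(V))
  if (V == 1L) phat <- matrix(phat, nrow = 1L,
                              dimnames = list(NULL, classes))
  prior <- sapply(classes, function(cl) mean(labels == cl))
  post <- t(apply(W_test, 1, function(w) {
    un <- sapply(classes, function(cl) prior[[cl]] * prod(phat[, cl]^w))
    un / sum(un)
  }))
  colnames(post) <- classes
  post
}
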