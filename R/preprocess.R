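the_epiletter_cache <- new.env(parent = emptyenv())

#' Default Dutch stop word list
#'
#' A frozen Dutch stop word list shipped with the package (common
#' determiners, prepositions, pronouns, auxiliaries and negations), so
#' that results do not drift with upstream library updates. Negations
#' (geen, niet, nooit, zonder) are deliberately present: they are removed
#' as unigrams but preserved inside bigrams by the retention rules.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  if (is.null(the_epiletter_cache$stopwords_nl)) {
    path <- system.file("extdata", "stopwords_nl.txt", package = "epiletter")
    con <- file(path, encoding = "UTF-8")
    on.exit(close(con))
    the_epiletter_cache$stopwords_nl <- readLines(con, warn = FALSE)
  }
  the_epiletter_cache$stopwords_nl
}

#' Preprocessing configuration for the n-gram arm
#'
#' Controls the tokenize - clean - lowercase - n-gram - stop word removal
#' pipeline. Stop words are removed *after* n-gram generation so that
#' informative bigrams survive even when their constituents are stop
#' words. Retention is expressed as three explicit mechanisms:
#' a bigram whitelist, a negation-first rule (`negations`), and a
#' pronoun + clinical-noun rule (`pronouns` with `keep_pronoun_with`).
#'
#' Numeric tokens are retained by default (ages and event frequencies may
#' be informative); hyphenated words are kept intact (Dutch compounds).
#'
#' @param nmax Maximum n-gram order (default 2: unigrams and bigrams).
#' @param connector String joining bigram constituents (default `"_"`);
#'   cleaned tokens never contain it.
#' @param stopwords Stop word list (default: the shipped Dutch list).
#' @param negations Tokens that, as the first constituent of a bigram,
#'   force its retention (e.g. `geen_koorts`, "no fever").
#' @param whitelist_bigrams Bigrams always retained, written with the
#'   connector (e.g. `"bij_opstaan"`, "on standing up").
#' @param pronouns,keep_pronoun_with A bigram pairing a pronoun with a
#'   listed clinical noun is retained (e.g. `haar_mond`, "her mouth").
#' @param strip_urls,strip_punct Drop URL tokens / punctuation-only
#'   tokens during cleaning.
#' @param drop_numbers Drop purely numeric tokens (default `FALSE`).
#' @param split_hyphens Split hyphenated words into parts (default
#'   `FALSE`).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(nmax = 2L,
                              connector = "_",
                              stopwords = default_stopwords(),
                              negations = c("geen", "niet", "nooit", "zonder"),
                              whitelist_bigrams = c("bij_opstaan", "na_inspanning"),
                              pronouns = c("haar", "zijn", "hij", "zij", "ze",
                                           "hem", "hun", "mijn", "uw", "je"),
                              keep_pronoun_with = c("mond", "ogen", "oog", "arm",
                                                    "armen", "been", "benen",
                                                    "hoofd", "tong", "lichaam",
                                                    "gezicht"),
                              strip_urls = TRUE,
                              strip_punct = TRUE,
                              drop_numbers = FALSE,
                              split_hyphens = FALSE) {
  stopifnot(nmax >= 1, nzchar(connector))
  structure(list(nmax = as.integer(nmax), connector = connector,
                 stopwords = stopwords, negations = negations,
                 whitelist_bigrams = whitelist_bigrams,
                 pronouns = pronouns, keep_pronoun_with = keep_pronoun_with,
                 strip_urls = strip_urls, strip_punct = strip_punct,
                 drop_numbers = drop_numbers, split_hyphens = split_hyphens),
            class = "preprocess_config")
}

url_pattern <- "^(https?://|www\\.)"

#' Tokenize letter text
#'
#' Splits on whitespace and punctuation boundaries while preserving
#' intra-word hyphens, apostrophes and diacritics. URLs survive
#' tokenization as single tokens (they are removed later during
#' cleaning), and a whitespace-delimited chunk consisting purely of
#' punctuation (e.g. an em-dash) is kept as a token for the cleaning
#' stage to drop.
#'
#' @param text A single character string.
#' @param config A [preprocess_config()].
#' @return Character vector of tokens, in order.
#' @export
tokenize <- function(text, config = preprocess_config()) {
  if (length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(character())
  }
  chunks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  word_pat <- if (config$split_hyphens) {
    "[\\p{L}\\p{N}]+(?:['’][\\p{L}\\p{N}]+)*"
  } else {
    "[\\p{L}\\p{N}]+(?:[-'’][\\p{L}\\p{N}]+)*"
  }
  is_url <- stringr::str_detect(chunks, url_pattern)
  words <- stringr::str_extract_all(chunks, word_pat)
  out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    if (is_url[i]) {
      out[[i]] <- chunks[i]
    } else if (length(words[[i]])) {
      out[[i]] <- words[[i]]
    } else {
      out[[i]] <- chunks[i]  # pure punctuation chunk
    }
  }
  unlist(out, use.names = FALSE)
}

#' Clean and lowercase tokens
#'
#' Removes punctuation-only tokens, symbols, separators and URLs, then
#' lowercases the remainder. Numeric tokens are retained unless
#' `drop_numbers` is set. Applying the function twice equals applying it
#' once.
#'
#' @param tokens Character vector from [tokenize()].
#' @param config A [preprocess_config()].
#' @return Cleaned, lowercased tokens.
#' @export
clean_and_lowercase <- function(tokens, config = preprocess_config()) {
  if (!length(tokens)) return(character())
  keep <- rep(TRUE, length(tokens))
  if (config$strip_punct) {
    keep <- keep & stringr::str_detect(tokens, "[\\p{L}\\p{N}]")
  }
  if (config$strip_urls) {
    keep <- keep & !stringr::str_detect(tokens, url_pattern)
  }
  if (config$drop_numbers) {
    keep <- keep & !stringr::str_detect(tokens, "^\\p{N}+$")
  }
  stringr::str_to_lower(tokens[keep])
}

#' Generate n-gram features
#'
#' Emits all unigrams in document order followed by all adjacent n-grams
#' up to order `nmax`, joined by the connector. For `nmax = 2` the output
#' length is `length(tokens) + max(0, length(tokens) - 1)`.
#'
#' @param tokens Cleaned, lowercased tokens.
#' @param config A [preprocess_config()].
#' @return Character vector of features.
#' @export
generate_ngrams <- function(tokens, config = preprocess_config()) {
  n <- length(tokens)
  if (!n) return(character())
  out <- list(tokens)
  if (config$nmax >= 2 && n >= 2) {
    for (k in 2:min(config$nmax, n)) {
      parts <- lapply(seq_len(k), function(j) tokens[j:(n - k + j)])
      out[[k]] <- do.call(paste, c(parts, sep = config$connector))
    }
  }
  unlist(out, use.names = FALSE)
}

#' Remove stop words after n-gram generation
#'
#' A unigram is dropped iff it is a stop word. An n-gram with a stop word
#' constituent is dropped unless (a) it is whitelisted, (b) its first
#' constituent is a negation, or (c) it pairs a pronoun with a listed
#' clinical noun. Removing stop words *after* n-gram generation is what
#' lets `geen_koorts` ("no_fever") survive while `geen` and `koorts`
#' would individually be removed.
#'
#' @param features Output of [generate_ngrams()].
#' @param config A [preprocess_config()].
#' @return Retained features, order preserved.
#' @export
remove_stopwords_postngram <- function(features, config = preprocess_config()) {
  if (!length(features)) return(character())
  is_ngram <- stringr::str_detect(features, stringr::fixed(config$connector))
  keep <- logical(length(features))
  # unigrams: drop iff stop word
  keep[!is_ngram] <- !(features[!is_ngram] %in% config$stopwords)
  if (any(is_ngram)) {
    grams <- features[is_ngram]
    parts <- strsplit(grams, config$connector, fixed = TRUE)
    keep[is_ngram] <- vapply(seq_along(grams), function(i) {
      p <- parts[[i]]
      if (!any(p %in% config$stopwords)) return(TRUE)
      if (grams[i] %in% config$whitelist_bigrams) return(TRUE)
      if (p[1] %in% config$negations) return(TRUE)
      if (length(p) == 2 &&
          ((p[1] %in% config$pronouns && p[2] %in% config$keep_pronoun_with) ||
           (p[2] %in% config$pronouns && p[1] %in% config$keep_pronoun_with))) {
        return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  features[keep]
}

#' Preprocess a corpus into n-gram documents
#'
#' Runs the full pipeline (tokenize, clean and lowercase, n-grams, stop
#' word removal) on every letter. The mapping is one letter to exactly
#' one n-gram document; documents may end up with zero features.
#'
#' @param corpus A `letter_corpus`.
#' @param config A [preprocess_config()].
#' @return An `ngram_docs` tibble with columns `id` and `features`
#'   (list-column of character vectors).
#' @export
preprocess_letters <- function(corpus, config = preprocess_config()) {
  feats <- lapply(corpus$anamnesis_text, function(txt) {
    remove_stopwords_postngram(
      generate_ngrams(
        clean_and_lowercase(tokenize(txt, config), config), config), config)
  })
  structure(tibble::tibble(id = corpus$id, features = feats),
            class = c("ngram_docs", class(tibble::tibble())))
}
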