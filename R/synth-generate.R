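# Build the item pool and the per-(class, stratum, site) probability
# tables implied by a synth_config. Items are the atomic draws: stop
# words (Zipf-decaying weights), background tokens (uniform weights),
# and signal items (base rate x multiplier, with the multiplier raised
# to ambiguity_shrink for initially-unclear letters). Letters with a
# final 'unclear' diagnosis are drawn from the 50/50 mixture of the two
# class distributions.
build_item_pool <- function(config) {
  v <- config$vocab
  sw <- v$stopwords
  bg <- v$background
  sigE <- v$epilepsy_signal
  sigN <- v$control_signal
  p0 <- v$signal_base_rate
  zipf <- (1 / seq_along(sw)) / sum(1 / seq_along(sw))
  items <- tibble::tibble(
    item = c(sw, bg, sigE$item, sigN$item),
    type = c(rep("stop", length(sw)), rep("background", length(bg)),
             rep("signal_epilepsy", nrow(sigE)),
             rep("signal_control", nrow(sigN))),
    base = c(v$stopword_mass * zipf,
             rep(v$background_mass / length(bg), length(bg)),
             rep(p0, nrow(sigE)), rep(p0, nrow(sigN))),
    multiplier = c(rep(1, length(sw) + length(bg)),
                   sigE$multiplier, sigN$multiplier)
  )
  items$tokens <- strsplit(items$item, " ", fixed = TRUE)
  items$words <- lengths(items$tokens)

  site_base <- function(site) {
    b <- items$base
    if (config$site_skew > 0 && site == "site_B") {
      is_bg <- items$type == "background"
      idx <- which(is_bg)
      half <- idx[seq_len(floor(length(idx) / 2))]
      b[half] <- b[half] * (1 + config$site_skew)
      b[setdiff(idx, half)] <- b[setdiff(idx, half)] * (1 - config$site_skew)
    }
    b
  }
  class_prob <- function(class, shrink, site) {
    b <- site_base(site)
    m <- rep(1, nrow(items))
    if (class == "epilepsy") {
      sel <- items$type == "signal_epilepsy"
      m[sel] <- items$multiplier[sel]^shrink
    } else {
      sel <- items$type == "signal_control"
      m[sel] <- items$multiplier[sel]^shrink
    }
    w <- b * m
    w / sum(w)
  }
  tables <- list()
  for (site in SITE_LEVELS) {
    for (stratum in c("clear", "unclear")) {
      shrink <- if (stratum == "unclear") config$ambiguity_shrink else 1
      pE <- class_prob("epilepsy", shrink, site)
      pN <- class_prob("no_epilepsy", shrink, site)
      tables[[paste(site, stratum, sep = ".")]] <-
        list(epilepsy = pE, no_epilepsy = pN, mixture = (pE + pN) / 2)
    }
  }
  list(items = items, tables = tables)
}

# Adjusted initially-unclear probability for letters with a definitive
# final diagnosis, so the overall initially-unclear rate matches
# p_initial_unclear while final-unclear letters are always initially
# unclear.
adjusted_p_unclear <- function(config) {
  p_unc <- config$final_dx_props[["unclear"]]
  max(0, min(1, (config$p_initial_unclear - p_unc) / (1 - p_unc)))
}

draw_length <- function(n, lm) {
  sigma <- sqrt(2 * log(lm$mean_target / lm$median_target))
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n - length(out), meanlog = log(lm$median_target),
                             sdlog = max(sigma, 1e-8)))
    out <- c(out, x[x >= lm$min_words & x <= lm$max_words])
  }
  out[seq_len(n)]
}

# Assemble sampled items into letter text: sentence scaffolding with
# 6-14 word sentences, a leading capital and a trailing period, so the
# tokenizer, cleaner and lowercaser all have real work to do.
assemble_text <- function(tokens) {
  n <- length(tokens)
  starts <- 1L
  while (TRUE) {
    nxt <- starts[length(starts)] + sample(6:14, 1)
    if (nxt > n) break
    starts <- c(starts, nxt)
  }
  ends <- c(starts[-1] - 1L, n)
  tokens[ends] <- paste0(tokens[ends], ".")
  tokens[starts] <- paste0(stringr::str_to_upper(substr(tokens[starts], 1, 1)),
                           substring(tokens[starts], 2))
  paste(tokens, collapse = " ")
}

#' Generate a synthetic letter corpus with known ground truth
#'
#' Draws `n_letters` letters according to the configuration: site, final
#' and initial diagnoses from their configured proportions, a word
#' length from the truncated log-normal length model, and letter text as
#' a token stream from the background + stop word + class-signal
#' mixture for the letter's class and stratum. The returned ground truth
#' records, for every letter, the realized signal-item counts, the total
#' item count and the exact generative log-likelihood under either
#' class, sufficient to recompute the Bayes-optimal decision for any
#' letter. Identical config and seed give a byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @return A list with `corpus` (a `letter_corpus`) and `truth` (a
#'   `ground_truth` object: per-letter records plus the generative
#'   parameter tables).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  pool <- build_item_pool(config)
  items <- pool$items
  sig_idx <- which(items$type %in% c("signal_epilepsy", "signal_control"))
  set.seed(config$seed)
  n <- config$n_letters

  site <- sample(SITE_LEVELS, n, replace = TRUE, prob = config$site_props)
  final_dx <- sample(DX_LEVELS, n, replace = TRUE, prob = config$final_dx_props)
  p_adj <- adjusted_p_unclear(config)
  initial_dx <- ifelse(final_dx == "unclear", "unclear",
                       ifelse(stats::runif(n) < p_adj, "unclear", final_dx))
  sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = c(0.546, 0.454))
  age <- round(pmin(pmax(stats::rlnorm(n, log(4.5), 0.9), 1 / 12), 17.8), 2)
  lens <- draw_length(n, config$length_model)

  text <- character(n)
  n_items <- integer(n)
  ll_e <- numeric(n)
  ll_n <- numeric(n)
  sig_counts <- vector("list", n)
  for (i in seq_len(n)) {
    stratum <- if (initial_dx[i] == "unclear") "unclear" else "clear"
    tab <- pool$tables[[paste(site[i], stratum, sep = ".")]]
    p <- switch(final_dx[i],
                epilepsy = tab$epilepsy,
                no_epilepsy = tab$no_epilepsy,
                unclear = tab$mixture)
    idx <- sample.int(nrow(items), size = lens[i], replace = TRUE, prob = p)
    n_items[i] <- length(idx)
    ll_e[i] <- sum(log(tab$epilepsy[idx]))
    ll_n[i] <- sum(log(tab$no_epilepsy[idx]))
    cnt <- tabulate(idx, nbins = nrow(items))[sig_idx]
    names(cnt) <- items$item[sig_idx]
    sig_counts[[i]] <- cnt[cnt > 0]
    text[i] <- assemble_text(unlist(items$tokens[idx], use.names = FALSE))
  }

  ids <- sprintf("L%05d", seq_len(n))
  corpus <- as_letter_corpus(
    tibble::tibble(id = ids, site = site, anamnesis_text = text, sex = sex,
                   age_years = age, initial_dx = initial_dx,
                   final_dx = final_dx),
    provenance = paste0("synthetic seed=", config$seed))
  truth <- structure(list(
    letters = tibble::tibble(id = ids, final_dx = final_dx,
                             initial_dx = initial_dx, n_items = n_items,
                             n_words = word_count(text),
                             loglik_epilepsy = ll_e,
                             loglik_no_epilepsy = ll_n,
                             signal_counts = sig_counts),
    params = pool, config = config), class = "ground_truth")
  list(corpus = corpus, truth = truth)
}

#' Write ground truth as a JSONL side-file
#'
#' @param truth A `ground_truth` from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  lt <- truth$letters
  lines <- vapply(seq_len(nrow(lt)), function(i) {
    jsonlite::toJSON(list(id = lt$id[i], final_dx = lt$final_dx[i],
                          initial_dx = lt$initial_dx[i],
                          n_items = lt$n_items[i], n_words = lt$n_words[i],
                          loglik_epilepsy = lt$loglik_epilepsy[i],
                          loglik_no_epilepsy = lt$loglik_no_epilepsy[i],
                          signal_counts = as.list(lt$signal_counts[[i]])),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Monte-Carlo Bayes-optimal accuracy of a synthetic configuration
#'
#' Generates `n_mc` letters restricted to the binary task (final
#' diagnosis epilepsy or no epilepsy), classifies each by the exact
#' generative log-likelihood ratio plus the binary log-prior ratio -
#' the decision rule no classifier trained on the text can beat on
#' average - and returns the fraction correct with its Monte-Carlo
#' standard error. Used as the performance ceiling that end-to-end model
#' accuracy is compared against.
#'
#' @param config A [synth_config()].
#' @param n_mc Number of Monte-Carlo letters (at least 100).
#' @param seed Seed for the Monte-Carlo draw (defaults to a child of the
#'   config seed).
#' @return A `bayes_oracle` list with `accuracy`, `se` and `n_mc`.
#' @export
oracle_bayes_accuracy <- function(config = synth_config(), n_mc = 2000L,
                                  seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (n_mc < 100) {
    stop("n_mc must be at least 100 (estimate too noisy below that)",
         call. = FALSE)
  }
  pool <- build_item_pool(config)
  items <- pool$items
  set.seed(seed %||% child_seed(config$seed, 977L))
  pri <- config$final_dx_props[BINARY_DX]
  pri <- pri / sum(pri)
  log_prior_ratio <- log(pri[["epilepsy"]] / pri[["no_epilepsy"]])
  p_adj <- adjusted_p_unclear(config)

  site <- sample(SITE_LEVELS, n_mc, replace = TRUE, prob = config$site_props)
  cls <- sample(BINARY_DX, n_mc, replace = TRUE, prob = pri)
  stratum <- ifelse(stats::runif(n_mc) < p_adj, "unclear", "clear")
  lens <- draw_length(n_mc, config$length_model)
  correct <- logical(n_mc)
  for (i in seq_len(n_mc)) {
    tab <- pool$tables[[paste(site[i], stratum[i], sep = ".")]]
    p <- if (cls[i] == "epilepsy") tab$epilepsy else tab$no_epilepsy
    idx <- sample.int(nrow(items), size = lens[i], replace = TRUE, prob = p)
    llr <- sum(log(tab$epilepsy[idx]) - log(tab$no_epilepsy[idx])) +
      log_prior_ratio
    pred <- if (llr > 0) "epilepsy" else "no_epilepsy"
    correct[i] <- pred == cls[i]
  }
  acc <- mean(correct)
  structure(list(accuracy = acc, se = sqrt(acc * (1 - acc) / n_mc),
                 n_mc = as.integer(n_mc)),
            class = "bayes_oracle")
}

#' @export
print.bayes_oracle <- function(x, ...) {
  cat(sprintf("<bayes_oracle> accuracy = %.4f (MC se = %.4f, n = %d)\n",
              x$accuracy, x$se, x$n_mc))
  invisible(x)
}

#' Letter length statistics
#'
#' Minimum, maximum, median and mean whitespace word counts of a corpus.
#'
#' @param corpus A non-empty `letter_corpus`.
#' @return List with `min`, `max`, `median`, `mean` (words).
#' @export
length_statistics <- function(corpus) {
  if (!nrow(corpus)) stop("empty corpus", call. = FALSE)
  wc <- word_count(corpus$anamnesis_text)
  list(min = min(wc), max = max(wc),
       median = stats::median(wc), mean = mean(wc))
}
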