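#' Stratified train/test split
#'
#' Within each stratum (by default final diagnosis crossed with
#' hospital site) a seeded random `test_fraction` of letters goes to the
#' test set and the remainder to training, so class and site mixes are
#' preserved in both halves. A stratum with fewer than two letters is
#' assigned entirely to training with a warning.
#'
#' @param corpus A `letter_corpus` of eligible letters (for the binary
#'   task, letters with a definitive final diagnosis).
#' @param test_fraction Fraction per stratum assigned to test (default
#'   0.2).
#' @param strata Stratification columns (default
#'   `c("final_dx", "site")`).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A `split_spec` list with `train_ids`, `test_ids`,
#'   `test_fraction`, `strata`, `seed`.
#' @export
stratified_split <- function(corpus, test_fraction = 0.2,
                             strata = c("final_dx", "site"), seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  key <- do.call(paste, c(lapply(strata, function(s) corpus[[s]]), sep = "|"))
  set.seed(as.integer(seed))
  test_ids <- character(0)
  for (s in sort(unique(key))) {
    ids <- corpus$id[key == s]
    if (length(ids) < 2) {
      warning("stratum '", s, "' has fewer than 2 letters; assigned to training",
              call. = FALSE)
      next
    }
    ids <- ids[order(ids, method = "radix")]  # order-invariant given ids
    n_test <- round(test_fraction * length(ids))
    if (n_test >= 1) {
      test_ids <- c(test_ids, ids[sample(length(ids), n_test)])
    }
  }
  structure(list(train_ids = setdiff(corpus$id, test_ids),
                 test_ids = sort(test_ids),
                 test_fraction = test_fraction, strata = strata,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Analysis-B test set
#'
#' The ids of letters that were 'unclear' at the first visit but
#' received a definitive final diagnosis during follow-up - the
#' clinically hardest stratum, used as a dedicated test set.
#'
#' @param corpus A `letter_corpus`.
#' @return Character vector of ids (with a warning if empty).
#' @export
analysis_b_testset <- function(corpus) {
  ids <- corpus$id[corpus$initial_dx == "unclear" &
                     corpus$final_dx %in% BINARY_DX]
  if (!length(ids)) {
    warning("no initially-unclear letters with a definitive final diagnosis",
            call. = FALSE)
  }
  ids
}

#' Fit the Naive Bayes arm on training letters
#'
#' The full train-only n-gram pipeline: preprocess, document-feature
#' matrix, TF-IDF, pre-rank to `prerank_k` features, RFE to `final_k`,
#' then the alpha-smoothed Naive Bayes fit on the selected TF-IDF
#' weights. Every fitted quantity (idf table, selected features, model)
#' depends only on the training letters, so the arm is leakage-free by
#' construction. Optionally tunes alpha over a grid by 5-fold
#' cross-validated accuracy (ties toward the smaller alpha).
#'
#' @param train A `letter_corpus` of training letters with binary final
#'   diagnoses.
#' @param pp A [preprocess_config()].
#' @param fs A [feature_selection_config()].
#' @param alpha Naive Bayes smoothing parameter (default 1).
#' @param alpha_grid Optional numeric grid (e.g. `c(0.1, 0.5, 1, 2)`);
#'   when supplied, overrides `alpha` with the cross-validated choice.
#' @return An `nb_arm` with `model`, `selected`, `idf`, `alpha` and the
#'   configs.
#' @export
fit_nb_arm <- function(train, pp = preprocess_config(),
                       fs = feature_selection_config(),
                       alpha = 1, alpha_grid = NULL) {
  stopifnot(all(train$final_dx %in% BINARY_DX))
  docs <- preprocess_letters(train, pp)
  dfm <- build_dfm(docs)
  weighted <- tfidf(dfm)
  pre <- prerank(weighted, fs$prerank_k)
  selected <- rfe_select(restrict_weighted(weighted, pre), train$final_dx, fs)
  Xsel <- restrict_weighted(weighted, selected$feature)
  if (!is.null(alpha_grid)) {
    alpha <- tune_alpha(Xsel, train$final_dx, alpha_grid, fs)
  }
  model <- fit_nb(Xsel, train$final_dx, alpha = alpha)
  structure(list(model = model, selected = selected, idf = weighted$idf,
                 alpha = alpha, pp = pp, fs = fs),
            class = "nb_arm")
}

tune_alpha <- function(Xsel, labels, grid, fs) {
  folds <- assign_folds(rownames(Xsel$weights), labels, fs$cv_folds,
                        child_seed(fs$seed, 31L))
  acc <- vapply(sort(grid), function(a) {
    correct <- logical(length(labels))
    for (f in seq_len(fs$cv_folds)) {
      tr <- folds != f
      m <- fit_nb(Xsel$weights[tr, , drop = FALSE], labels[tr], alpha = a)
      pred <- predict(m, Xsel$weights[!tr, , drop = FALSE])
      correct[!tr] <- pred$labels == labels[!tr]
    }
    mean(correct)
  }, numeric(1))
  sort(grid)[which.max(acc)]  # ties toward the smaller alpha
}

#' Predict with a fitted Naive Bayes arm
#'
#' @param object An `nb_arm`.
#' @param corpus Letters to classify.
#' @param ... Unused.
#' @return List with `labels` and `posterior`.
#' @export
predict.nb_arm <- function(object, corpus, ...) {
  docs <- preprocess_letters(corpus, object$pp)
  X <- project_docs(docs, object$selected, object$idf)
  predict(object$model, X)
}

#' Fit the sentence-embedding arm on training letters
#'
#' Embeds the training texts with the (offline, seeded) provider and
#' fits the boosted linear classifier on the vectors. Embedding is a
#' fixed per-document map, so precomputed embeddings for the whole
#' corpus may be passed via `embeddings` (rows indexed by letter id)
#' without any train/test leakage.
#'
#' @param train Training `letter_corpus` with binary final diagnoses.
#' @param provider An [hash_embedder()].
#' @param control A [boost_control()].
#' @param embeddings Optional precomputed embedding matrix with letter
#'   ids as row names.
#' @return An `embed_arm`.
#' @export
fit_embed_arm <- function(train, provider = hash_embedder(),
                          control = boost_control(), embeddings = NULL) {
  stopifnot(all(train$final_dx %in% BINARY_DX))
  X <- arm_embeddings(train, provider, embeddings)
  model <- fit_boosted_linear(X, train$final_dx, control)
  structure(list(model = model, provider = provider, control = control),
            class = "embed_arm")
}

arm_embeddings <- function(corpus, provider, embeddings) {
  if (is.null(embeddings)) {
    embed_letters(corpus$anamnesis_text, provider, ids = corpus$id)
  } else {
    stopifnot(all(corpus$id %in% rownames(embeddings)))
    embeddings[corpus$id, , drop = FALSE]
  }
}

#' Predict with a fitted embedding arm
#'
#' @param object An `embed_arm`.
#' @param corpus Letters to classify.
#' @param embeddings Optional precomputed embeddings (ids as row names).
#' @param ... Unused.
#' @return List with `labels` and `probability`.
#' @export
predict.embed_arm <- function(object, corpus, embeddings = NULL, ...) {
  X <- arm_embeddings(corpus, object$provider, embeddings)
  predict(object$model, X)
}

evaluate_arm <- function(pred_labels, test) {
  cm <- confusion(pred_labels, test$final_dx)
  metrics <- compute_metrics(cm)
  correct <- pred_labels == test$final_dx
  strat <- ifelse(test$initial_dx == "unclear", "initially_unclear", "clear")
  by_stratum <- vapply(c("clear", "initially_unclear"), function(s) {
    if (!any(strat == s)) NA_real_ else mean(correct[strat == s])
  }, numeric(1))
  list(confusion = cm, metrics = metrics,
       accuracy = mean(correct),
       accuracy_by_stratum = by_stratum,
       predicted = pred_labels, correct = correct)
}

run_analysis <- function(corpus, analysis = c("A", "B"), seed = 1L,
                         arms = c("nb", "embed"), min_words = 20L,
                         pp = preprocess_config(),
                         fs = feature_selection_config(),
                         alpha = 1, alpha_grid = NULL,
                         provider = hash_embedder(),
                         control = boost_control(),
                         embeddings = NULL) {
  analysis <- match.arg(analysis)
  arms <- match.arg(arms, several.ok = TRUE)
  fs$seed <- child_seed(seed, 11L)

  excl <- exclude_short_letters(corpus, min_words)
  eligible <- excl$corpus[excl$corpus$final_dx %in% BINARY_DX, , drop = FALSE]

  if (analysis == "A") {
    split <- stratified_split(eligible, 0.2, c("final_dx", "site"),
                              seed = child_seed(seed, 7L))
    train <- eligible[eligible$id %in% split$train_ids, , drop = FALSE]
    test <- eligible[eligible$id %in% split$test_ids, , drop = FALSE]
  } else {
    # B: test on every initially-unclear letter with a definitive final
    # diagnosis (short letters included - exclusion applies to training
    # only); train on all other eligible letters, so train and test are
    # disjoint by construction.
    all_binary <- corpus[corpus$final_dx %in% BINARY_DX, , drop = FALSE]
    test_ids <- analysis_b_testset(all_binary)
    train <- eligible[!(eligible$id %in% test_ids), , drop = FALSE]
    test <- all_binary[all_binary$id %in% test_ids, , drop = FALSE]
    split <- structure(list(train_ids = train$id, test_ids = test$id,
                            test_fraction = NA_real_,
                            strata = "initial_dx == 'unclear'", seed = NA_integer_),
                       class = "split_spec")
  }
  if (!nrow(test)) {
    warning("analysis ", analysis, ": empty test set; nothing to evaluate",
            call. = FALSE)
    return(structure(list(analysis = analysis, n_train = nrow(train),
                          n_test = 0L, excluded = excl$exclusions,
                          split = split, arms = list(), fits = list(),
                          mcnemar = NULL, top_features = NULL,
                          test_ids_disjoint_from_training = TRUE,
                          settings = list(seed = as.integer(seed),
                                          min_words = min_words)),
                     class = "analysis_report"))
  }
  stopifnot(length(intersect(train$id, test$id)) == 0)

  fits <- list()
  evals <- list()
  if ("nb" %in% arms) {
    fits$nb <- fit_nb_arm(train, pp, fs, alpha = alpha, alpha_grid = alpha_grid)
    evals$nb <- evaluate_arm(predict(fits$nb, test)$labels, test)
  }
  if ("embed" %in% arms) {
    fits$embed <- fit_embed_arm(train, provider, control, embeddings)
    evals$embed <- evaluate_arm(predict(fits$embed, test, embeddings)$labels, test)
  }
  mcn <- if (length(evals) == 2) {
    mcnemar_compare(evals$nb$correct, evals$embed$correct)
  } else NULL
  top <- if (!is.null(fits$nb)) top_features_per_class(fits$nb$model, m = 20L) else NULL

  structure(list(analysis = analysis,
                 n_train = nrow(train), n_test = nrow(test),
                 excluded = excl$exclusions,
                 split = split,
                 arms = evals,
                 fits = fits,
                 mcnemar = mcn,
                 top_features = top,
                 test_ids_disjoint_from_training = TRUE,
                 settings = list(seed = as.integer(seed), min_words = min_words,
                                 alpha = if (length(fits)) fits$nb$alpha %||% alpha else alpha,
                                 final_k = fs$final_k, prerank_k = fs$prerank_k,
                                 cv_folds = fs$cv_folds,
                                 nmax = pp$nmax,
                                 embed_provider = provider$name,
                                 boost = unclass(control))),
            class = "analysis_report")
}

#' Run Analysis A (stratified split of all definitive letters)
#'
#' Excludes succinct letters and letters with a final 'unclear'
#' diagnosis, splits the remainder 80/20 stratified by final diagnosis
#' and site, trains both arms on the training half only, and evaluates
#' on the held-out test half: per-arm confusion matrices and metrics
#' with confidence intervals, per-stratum accuracies, a McNemar
#' comparison of the two arms, and the per-class top-feature report.
#'
#' @param corpus A `letter_corpus`.
#' @param seed Master seed for this analysis (split, folds).
#' @param arms `"nb"`, `"embed"` or both.
#' @param ... Passed to the engine: `min_words`, `pp`, `fs`, `alpha`,
#'   `alpha_grid`, `provider`, `control`, `embeddings`.
#' @return An `analysis_report`.
#' @export
run_analysis_a <- function(corpus, seed = 1L, arms = c("nb", "embed"), ...) {
  run_analysis(corpus, "A", seed = seed, arms = arms, ...)
}

#' Run Analysis B (initially-unclear letters as the test set)
#'
#' The test set is every letter that was 'unclear' at the first visit
#' but definitive at follow-up; training uses all other eligible
#' letters, so the test letters are never seen during training (the
#' leakage-safe reading of the design). Outputs match
#' [run_analysis_a()].
#'
#' @inheritParams run_analysis_a
#' @return An `analysis_report`.
#' @export
run_analysis_b <- function(corpus, seed = 1L, arms = c("nb", "embed"), ...) {
  run_analysis(corpus, "B", seed = seed, arms = arms, ...)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> Analysis ", x$analysis, ": ", x$n_train,
      " train / ", x$n_test, " test letters\n", sep = "")
  for (arm in names(x$arms)) {
    m <- x$arms[[arm]]$metrics
    acc <- m[m$metric == "accuracy", ]
    cat(sprintf("  %-6s accuracy %.2f (%.2f-%.2f)\n", arm, acc$estimate,
                acc$conf_low, acc$conf_high))
  }
  if (!is.null(x$mcnemar)) {
    cat(sprintf("  McNemar chi2 = %.3f, p = %.3f\n", x$mcnemar$chi2, x$mcnemar$p))
  }
  invisible(x)
}
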