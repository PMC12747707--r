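#' Build a document-feature matrix
#'
#' Sparse documents-by-features count matrix (Bag-of-Words). Features are
#' those observed in at least one document, ordered lexicographically for
#' determinism.
#'
#' @param docs An `ngram_docs` tibble from [preprocess_letters()], or a
#'   named list of character feature vectors.
#' @return A sparse `dgCMatrix` with document ids as row names and
#'   feature names as column names.
#' @export
build_dfm <- function(docs) {
  if (inherits(docs, "data.frame")) {
    ids <- docs$id
    feats <- docs$features
  } else {
    ids <- names(docs)
    feats <- docs
  }
  if (!length(ids)) stop("no documents supplied", call. = FALSE)
  lens <- lengths(feats)
  if (sum(lens) == 0) {
    stop("all documents are empty after preprocessing", call. = FALSE)
  }
  vocab <- sort(unique(unlist(feats, use.names = FALSE)), method = "radix")
  j <- match(unlist(feats, use.names = FALSE), vocab)
  i <- rep(seq_along(ids), lens)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(ids), length(vocab)),
                            dimnames = list(ids, vocab))
  methods::as(m, "CsparseMatrix")
}

#' TF-IDF weighting
#'
#' Weights each count as `count * log10(N / df)` where `df` is the number
#' of documents containing the feature. The per-feature idf table is
#' retained so that new (test) documents can be projected with training
#' idf values only. A feature present in every document receives idf 0
#' and therefore all-zero weights.
#'
#' @param dfm Sparse count matrix from [build_dfm()].
#' @return A `weighted_dfm`: list with `weights` (sparse matrix), `idf`
#'   (named numeric) and `n_docs`.
#' @export
tfidf <- function(dfm) {
  n <- nrow(dfm)
  stopifnot(n >= 1)
  df <- Matrix::colSums(dfm != 0)
  idf <- log10(n / df)
  w <- dfm %*% Matrix::Diagonal(x = idf)
  dimnames(w) <- dimnames(dfm)
  structure(list(weights = methods::as(w, "CsparseMatrix"),
                 idf = stats::setNames(as.numeric(idf), colnames(dfm)),
                 n_docs = n),
            class = "weighted_dfm")
}

#' @export
print.weighted_dfm <- function(x, ...) {
  cat("<weighted_dfm> ", nrow(x$weights), " docs x ", ncol(x$weights),
      " features (TF-IDF, idf = log10(N/df))\n", sep = "")
  invisible(x)
}

restrict_weighted <- function(weighted, features) {
  structure(list(weights = weighted$weights[, features, drop = FALSE],
                 idf = weighted$idf[features],
                 n_docs = weighted$n_docs),
            class = "weighted_dfm")
}

#' Pre-rank features by total TF-IDF mass
#'
#' Returns the `k` features with the largest TF-IDF column sums (ties
#' broken lexicographically), the pre-selection step that caps the
#' vocabulary entering recursive feature elimination. If fewer than `k`
#' features exist, all are returned.
#'
#' @param weighted A `weighted_dfm`.
#' @param k Number of features to keep (default 8000).
#' @return Character vector of feature names.
#' @export
prerank <- function(weighted, k = 8000L) {
  stopifnot(k >= 1)
  cs <- Matrix::colSums(weighted$weights)
  nm <- colnames(weighted$weights)
  ord <- order(-cs, nm, method = "radix")
  nm[ord][seq_len(min(k, length(nm)))]
}

#' Feature selection configuration
#'
#' @param prerank_k Features entering RFE after pre-ranking (default
#'   8000).
#' @param final_k Features retained by RFE (default 300, roughly one
#'   feature per five training cases at study scale).
#' @param cv_folds Cross-validation folds for the importance estimate
#'   (default 5).
#' @param elimination_fraction Fraction of remaining features dropped per
#'   RFE round (default 0.1).
#' @param alpha Additive smoothing used inside the importance estimator.
#' @param seed Integer seed for fold assignment.
#' @return A `feature_selection_config` list.
#' @export
feature_selection_config <- function(prerank_k = 8000L, final_k = 300L,
                                     cv_folds = 5L,
                                     elimination_fraction = 0.1,
                                     alpha = 1, seed = 1L) {
  stopifnot(final_k <= prerank_k, cv_folds >= 2,
            elimination_fraction > 0, elimination_fraction < 1, alpha > 0)
  structure(list(prerank_k = as.integer(prerank_k),
                 final_k = as.integer(final_k),
                 cv_folds = as.integer(cv_folds),
                 elimination_fraction = elimination_fraction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "feature_selection_config")
}

# Fold assignment that is stratified by label, seeded, and invariant to
# document order: documents are ranked by id before the shuffled fold
# labels are dealt out.
assign_folds <- function(ids, labels, k, seed) {
  folds <- integer(length(ids))
  set.seed(seed)
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[order(ids[idx], method = "radix")]
    folds[idx] <- rep_len(seq_len(k), length(idx))[sample(length(idx))]
  }
  folds
}

#' Recursive feature elimination with cross-validated NB importance
#'
#' Starting from the supplied (pre-ranked) feature set, each round
#' estimates per-feature importance as the cross-validated mean magnitude
#' of the alpha-smoothed Naive Bayes class-conditional log-likelihood
#' difference, `|log P(f|epilepsy) - log P(f|no_epilepsy)|`, weighted by
#' the feature's overall TF-IDF mass, and eliminates the lowest
#' `elimination_fraction`. When at most `final_k` features remain the set
#' is truncated to exactly `final_k` by importance. Deterministic given
#' the seed; ties break lexicographically.
#'
#' @param weighted A `weighted_dfm` on the training documents, already
#'   restricted to the pre-ranked vocabulary (see [prerank()]).
#' @param labels Binary labels (`"epilepsy"` / `"no_epilepsy"`) aligned
#'   to rows.
#' @param config A [feature_selection_config()].
#' @return A `selected_features` tibble `(feature, importance)` in
#'   decreasing importance order.
#' @export
rfe_select <- function(weighted, labels, config = feature_selection_config()) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("rfe_select requires both classes in `labels`", call. = FALSE)
  }
  stopifnot(all(labels %in% BINARY_DX),
            length(labels) == nrow(weighted$weights))
  W <- weighted$weights
  feats <- colnames(W)
  alpha <- config$alpha
  k <- config$cv_folds
  folds <- assign_folds(rownames(W), labels, k, config$seed)

  # Per-fold, per-class column sums never change across rounds: cache
  # them once; each round only re-derives denominators over the active
  # set.
  sums_e <- Matrix::colSums(W[labels == "epilepsy", , drop = FALSE])
  sums_n <- Matrix::colSums(W[labels == "no_epilepsy", , drop = FALSE])
  fold_e <- lapply(seq_len(k), function(f)
    sums_e - Matrix::colSums(W[labels == "epilepsy" & folds == f, , drop = FALSE]))
  fold_n <- lapply(seq_len(k), function(f)
    sums_n - Matrix::colSums(W[labels == "no_epilepsy" & folds == f, , drop = FALSE]))
  mass <- sums_e + sums_n

  importance_of <- function(active) {
    V <- length(active)
    imp <- numeric(V)
    for (f in seq_len(k)) {
      se <- fold_e[[f]][active]
      sn <- fold_n[[f]][active]
      # Moderated log-ratio: the pseudocount is alpha scaled to the
      # average per-class feature mass, so rare features with extreme
      # splits are shrunk toward 0 instead of dominating the ranking
      # (the prior-count device of moderated differential-abundance
      # statistics).
      prior <- alpha * (sum(se) + sum(sn)) / (2 * V)
      de <- sum(se) + prior * V
      dn <- sum(sn) + prior * V
      imp <- imp + abs(log(se + prior) - log(de) - log(sn + prior) + log(dn))
    }
    (imp / k) * mass[active]
  }

  active <- feats
  repeat {
    imp <- importance_of(active)
    ord <- order(-imp, active, method = "radix")
    active <- active[ord]
    imp <- imp[ord]
    if (length(active) <= config$final_k) break
    n_drop <- max(1L, floor(config$elimination_fraction * length(active)))
    n_drop <- min(n_drop, length(active) - config$final_k)
    active <- active[seq_len(length(active) - n_drop)]
  }
  structure(tibble::tibble(feature = active, importance = imp),
            class = c("selected_features", class(tibble::tibble())))
}

#' Project documents onto selected training features
#'
#' Represents (test) documents on exactly the selected training features
#' using the *training* idf values; features unseen in training are
#' ignored, so no information flows from test to train.
#'
#' @param docs An `ngram_docs` tibble.
#' @param selected A `selected_features` tibble (or character vector of
#'   feature names).
#' @param idf Named idf table retained by [tfidf()] on the training set.
#' @return A `weighted_dfm` on the selected features.
#' @export
project_docs <- function(docs, selected, idf) {
  feats <- if (is.character(selected)) selected else selected$feature
  if (!length(feats)) stop("empty selected feature set", call. = FALSE)
  stopifnot(all(feats %in% names(idf)))
  counts <- vapply(docs$features, function(fv) {
    tabulate(match(fv, feats), nbins = length(feats))
  }, numeric(length(feats)))
  counts <- if (length(feats) == 1L) matrix(counts, ncol = 1L) else t(counts)
  dimnames(counts) <- list(docs$id, feats)
  w <- methods::as(counts %*% diag(x = idf[feats], nrow = length(feats)),
                   "CsparseMatrix")
  dimnames(w) <- list(docs$id, feats)
  structure(list(weights = w, idf = idf[feats], n_docs = nrow(w)),
            class = "weighted_dfm")
}

#' Most class-characteristic features
#'
#' Ranks the fitted vocabulary by the class-conditional log-likelihood
#' ratio and returns, for each class, the `m` features most in its
#' favour with their scores - the per-class keyword report.
#'
#' @param model An `nb_model`.
#' @param m Features per class (default 20; truncated to the vocabulary
#'   size).
#' @return A list of two tibbles, `epilepsy` and `no_epilepsy`, each
#'   `(feature, score)` with score the log-likelihood ratio favouring
#'   that class.
#' @export
top_features_per_class <- function(model, m = 20L) {
  stopifnot(inherits(model, "nb_model"))
  llr <- model$feature_loglik[, "epilepsy"] - model$feature_loglik[, "no_epilepsy"]
  feats <- rownames(model$feature_loglik)
  m <- min(m, length(feats))
  if (m == 0L) {
    empty <- tibble::tibble(feature = character(), score = numeric())
    return(structure(list(epilepsy = empty, no_epilepsy = empty),
                     class = "top_features"))
  }
  ord_e <- order(-llr, feats, method = "radix")[seq_len(m)]
  ord_n <- order(llr, feats, method = "radix")[seq_len(m)]
  structure(list(
    epilepsy = tibble::tibble(feature = feats[ord_e], score = llr[ord_e]),
    no_epilepsy = tibble::tibble(feature = feats[ord_n], score = -llr[ord_n])
  ), class = "top_features")
}

#' @export
print.top_features <- function(x, n = 10L, ...) {
  cat("<top_features>\n  epilepsy: ",
      paste(utils::head(x$epilepsy$feature, n), collapse = ", "),
      "\n  no_epilepsy: ",
      paste(utils::head(x$no_epilepsy$feature, n), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
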