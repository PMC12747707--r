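#' Fit a multinomial Naive Bayes classifier on TF-IDF weights
#'
#' Bayes' theorem under a strong feature-independence assumption, with
#' additive (alpha) smoothing so that no class-conditional feature
#' probability is zero:
#' `P(f|c) = (sum_i w_if + alpha) / (sum_i sum_g w_ig + alpha * V)`,
#' accumulated over the training documents of class `c`. Accepts
#' fractional accumulations, so it can be fitted directly on TF-IDF
#' weights (the multinomial event model on weighted counts). Class
#' priors are the training label frequencies.
#'
#' @param X A `weighted_dfm` or a (sparse) matrix of non-negative
#'   feature weights, documents in rows.
#' @param labels Binary labels (`"epilepsy"` / `"no_epilepsy"`) aligned
#'   to rows; both classes must be present.
#' @param alpha Positive smoothing parameter (default 1).
#' @return An `nb_model` with `log_priors`, `feature_loglik`
#'   (vocabulary-by-class), `alpha` and `vocabulary`.
#' @export
fit_nb <- function(X, labels, alpha = 1) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  W <- if (inherits(X, "weighted_dfm")) X$weights else X
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(W))
  if (!all(BINARY_DX %in% labels)) {
    stop("fit_nb requires both classes in `labels`", call. = FALSE)
  }
  vocab <- colnames(W)
  V <- length(vocab)
  loglik <- vapply(BINARY_DX, function(cl) {
    s <- Matrix::colSums(W[labels == cl, , drop = FALSE])
    log(s + alpha) - log(sum(s) + alpha * V)
  }, numeric(V))
  if (V == 1L) loglik <- matrix(loglik, nrow = 1L,
                                dimnames = list(vocab, BINARY_DX))
  rownames(loglik) <- vocab
  n_c <- c(epilepsy = sum(labels == "epilepsy"),
           no_epilepsy = sum(labels == "no_epilepsy"))
  structure(list(classes = BINARY_DX,
                 log_priors = log(n_c / sum(n_c)),
                 feature_loglik = loglik,
                 alpha = alpha,
                 vocabulary = vocab),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> multinomial Naive Bayes, ", length(x$vocabulary),
      " features, alpha = ", x$alpha,
      ", priors = (", paste(sprintf("%.3f", exp(x$log_priors)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Predict with a Naive Bayes model
#'
#' Per document, the log-posterior score of class `c` is
#' `log_prior_c + sum_f w_f * log P(f|c)`; posteriors are the softmax of
#' the two scores. Ties are broken toward `no_epilepsy` (a false
#' positive medicates unnecessarily, so the positive call requires
#' strictly stronger evidence). A document with an all-zero row gets the
#' priors as its posterior.
#'
#' @param object An `nb_model`.
#' @param newdata A `weighted_dfm` or matrix on the model vocabulary.
#' @param ... Unused.
#' @return List with `labels` (character) and `posterior` (matrix with
#'   columns `epilepsy`, `no_epilepsy`, rows summing to 1).
#' @export
predict.nb_model <- function(object, newdata, ...) {
  W <- if (inherits(newdata, "weighted_dfm")) newdata$weights else newdata
  if (ncol(W) != length(object$vocabulary) ||
      !identical(colnames(W), object$vocabulary)) {
    stop("vocabulary mismatch between model and newdata", call. = FALSE)
  }
  scores <- as.matrix(W %*% object$feature_loglik)
  scores <- sweep(scores, 2, object$log_priors, "+")
  mx <- apply(scores, 1, max)
  post <- exp(scores - mx)
  post <- post / rowSums(post)
  labels <- ifelse(post[, "epilepsy"] > post[, "no_epilepsy"],
                   "epilepsy", "no_epilepsy")
  list(labels = unname(labels), posterior = unname(post) |>
         (\(p) {colnames(p) <- BINARY_DX; rownames(p) <- rownames(W); p})())
}
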