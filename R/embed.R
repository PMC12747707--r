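#' Offline hash-projection embedding provider
#'
#' The default, fully offline embedding backend: each text is normalized
#' (lowercased, diacritics folded to their lexical equivalents,
#' punctuation stripped, whitespace squashed), its token multiset is
#' hashed into `n_buckets` buckets with a seeded polynomial hash, and the
#' bucket-count vector is passed through a fixed seeded Gaussian random
#' projection to `dim` dimensions. The map is deterministic: the same
#' text always yields the same vector, and no network access or model
#' download is ever needed. Texts sharing most of their tokens land
#' close in cosine similarity.
#'
#' @param dim Output dimension (default 768, the sentence-embedding
#'   convention this provider mirrors).
#' @param n_buckets Hash buckets before projection (default 4096).
#' @param seed Seed fixing both the hash mixing and the projection.
#' @return An `embedding_provider`.
#' @export
hash_embedder <- function(dim = 768L, n_buckets = 4096L, seed = 1L) {
  set.seed(as.integer(seed))
  projection <- matrix(stats::rnorm(n_buckets * dim) / sqrt(dim),
                       nrow = n_buckets, ncol = dim)
  structure(list(name = sprintf("hash-projection-%dd", dim),
                 dim = as.integer(dim),
                 n_buckets = as.integer(n_buckets),
                 seed = as.integer(seed),
                 deterministic = TRUE,
                 projection = projection),
            class = "embedding_provider")
}

#' Online pretrained-encoder provider (not available offline)
#'
#' Placeholder constructor for a pretrained multilingual sentence
#' encoder backend. Such a backend requires a model download, which this
#' package deliberately never performs; calling this function raises an
#' error instructing use of the offline [hash_embedder()] provider.
#'
#' @param model Model identifier.
#' @export
pretrained_embedder <- function(model = "paraphrase-multilingual-mpnet-base-v2") {
  stop("pretrained encoder backend '", model, "' is not available in this ",
       "installation (it requires a network download); use the offline ",
       "hash_embedder() provider instead", call. = FALSE)
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$name, " (", x$n_buckets, " buckets, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

# Provider-side normalizer: the embedding arm uses a lighter pipeline
# than the n-gram arm. Exact rules: lowercase; fold diacritics to ASCII
# lexical equivalents; replace every non-alphanumeric character with a
# space; squash whitespace.
normalize_for_embedding <- function(text) {
  x <- stringr::str_to_lower(text)
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_squish(x)
}

# Seeded 31-bit polynomial rolling hash of a token's UTF-8 bytes.
hash_token <- function(token, seed, n_buckets) {
  h <- (as.numeric(seed) * 2654435761) %% 1000000007
  for (b in utf8ToInt(token)) {
    h <- (h * 131 + b) %% 1000000007
  }
  as.integer(h %% n_buckets) + 1L
}

#' Embed letter texts
#'
#' One `dim`-length vector per text, produced by the provider. Empty
#' texts map to the zero vector with a warning.
#'
#' @param texts Character vector.
#' @param provider An [hash_embedder()] provider.
#' @param ids Optional row names for the result.
#' @return Numeric matrix, `length(texts)` by `provider$dim`.
#' @export
embed_letters <- function(texts, provider = hash_embedder(), ids = NULL) {
  stopifnot(inherits(provider, "embedding_provider"))
  norm <- normalize_for_embedding(texts)
  toks <- strsplit(norm, " ", fixed = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  if (any(lengths(toks) == 0)) {
    warning("empty text(s) embedded as zero vector", call. = FALSE)
  }
  vocab <- unique(unlist(toks, use.names = FALSE))
  buckets <- vapply(vocab, hash_token, integer(1),
                    seed = provider$seed, n_buckets = provider$n_buckets)
  lens <- lengths(toks)
  if (sum(lens)) {
    counts <- Matrix::sparseMatrix(
      i = rep(seq_along(toks), lens),
      j = buckets[match(unlist(toks, use.names = FALSE), vocab)],
      x = 1, dims = c(length(toks), provider$n_buckets))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                   dims = c(length(toks), provider$n_buckets))
  }
  emb <- as.matrix(counts %*% provider$projection)
  rownames(emb) <- ids
  emb
}

#' Boosted linear classifier hyperparameters
#'
#' Pinned "default hyperparameters" of the boosted linear binary
#' classifier, fixed in the package so runs are reproducible.
#'
#' @param n_rounds Boosting rounds (default 100).
#' @param learning_rate Shrinkage per update (default 0.5).
#' @param l2_penalty L2 regularization strength (default 0.1).
#' @param threshold Probability cut for the positive (epilepsy) call,
#'   in (0, 1); default 0.5, no threshold tuning.
#' @return A `boost_control` list.
#' @export
boost_control <- function(n_rounds = 100L, learning_rate = 0.5,
                          l2_penalty = 0.1, threshold = 0.5) {
  stopifnot(n_rounds >= 1, learning_rate > 0, l2_penalty >= 0,
            threshold > 0, threshold < 1)
  structure(list(n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 l2_penalty = l2_penalty,
                 threshold = threshold),
            class = "boost_control")
}

#' Fit a boosted linear binary classifier
#'
#' Additive boosting on the logistic loss with linear base learners:
#' each round refreshes the gradient and curvature of the loss and makes
#' one cyclic pass of regularized Newton coordinate updates, each scaled
#' by the learning rate - gradient boosting in which the trees are
#' replaced by additive linear updates. The iterate converges toward the
#' L2-regularized logistic optimum and the fit is deterministic given
#' the data (no subsampling).
#'
#' @param X Dense numeric feature matrix (documents by dimensions), e.g.
#'   from [embed_letters()]. All entries must be finite.
#' @param labels Binary labels (`"epilepsy"` / `"no_epilepsy"`).
#' @param control A [boost_control()].
#' @return A `boosted_linear` model with `weights`, `bias`,
#'   `hyperparams` and `threshold`.
#' @export
fit_boosted_linear <- function(X, labels, control = boost_control()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  if (!all(BINARY_DX %in% labels)) {
    stop("fit_boosted_linear requires both classes", call. = FALSE)
  }
  y <- as.numeric(labels == "epilepsy")
  d <- ncol(X)
  lr <- control$learning_rate
  l2 <- control$l2_penalty
  w <- numeric(d)
  b <- 0
  eta <- numeric(nrow(X))
  for (round in seq_len(control$n_rounds)) {
    p <- stats::plogis(eta)
    r <- p - y
    h <- pmax(p * (1 - p), 1e-6)
    # intercept update (unpenalized)
    db <- -lr * sum(r) / sum(h)
    b <- b + db
    eta <- eta + db
    r <- r + h * db
    for (j in seq_len(d)) {
      xj <- X[, j]
      g <- sum(r * xj) + l2 * w[j]
      hj <- sum(h * xj * xj) + l2
      dj <- -lr * g / hj
      w[j] <- w[j] + dj
      eta <- eta + xj * dj
      r <- r + h * xj * dj
    }
  }
  structure(list(weights = stats::setNames(w, colnames(X)),
                 bias = b,
                 hyperparams = control,
                 threshold = control$threshold),
            class = "boosted_linear")
}

#' @export
print.boosted_linear <- function(x, ...) {
  cat("<boosted_linear> ", length(x$weights), " weights, ",
      x$hyperparams$n_rounds, " rounds, lr = ", x$hyperparams$learning_rate,
      ", l2 = ", x$hyperparams$l2_penalty, "\n", sep = "")
  invisible(x)
}

#' Predict with a boosted linear classifier
#'
#' Probability is `logistic(w . x + b)`; the label is `epilepsy` iff the
#' probability strictly exceeds the threshold.
#'
#' @param object A `boosted_linear` model.
#' @param newdata Numeric matrix with matching dimension.
#' @param ... Unused.
#' @return List with `labels` and `probability` (of epilepsy).
#' @export
predict.boosted_linear <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    stop("dimension mismatch: model has ", length(object$weights),
         " weights, newdata has ", ncol(newdata), " columns", call. = FALSE)
  }
  p <- stats::plogis(as.numeric(newdata %*% object$weights + object$bias))
  list(labels = ifelse(p > object$threshold, "epilepsy", "no_epilepsy"),
       probability = p)
}
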