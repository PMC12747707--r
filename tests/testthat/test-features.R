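toy_docs <- function(feature_lists, ids = sprintf("d%d", seq_along(feature_lists))) {
  structure(tibble::tibble(id = ids, features = feature_lists),
            class = c("ngram_docs", class(tibble::tibble())))
}

test_that("the document-feature matrix counts occurrences with lexicographic features", {
  dfm <- build_dfm(toy_docs(list(c("a", "a", "b"), "a")))
  expect_equal(as.matrix(dfm),
               matrix(c(2, 1, 1, 0), 2, 2,
                      dimnames = list(c("d1", "d2"), c("a", "b"))))
  one <- build_dfm(toy_docs(list(c("x", "y"))))
  expect_equal(nrow(one), 1L)
  expect_error(build_dfm(toy_docs(list(character(), character()))),
               "empty after preprocessing")
})

test_that("row sums equal per-document feature counts on synthetic docs", {
  gen <- generate_corpus(small_cfg(n = 50, seed = 17))
  docs <- preprocess_letters(gen$corpus)
  dfm <- build_dfm(docs)
  expect_equal(unname(Matrix::rowSums(dfm)), lengths(docs$features))
})

test_that("tfidf implements count x log10(N/df) and keeps the idf table", {
  w <- tfidf(build_dfm(toy_docs(list(c("rare", "both"), "both"))))
  expect_equal(w$weights["d1", "rare"], log10(2), tolerance = 1e-12)
  # feature present in all documents weights to zero
  expect_equal(unname(w$weights[, "both"]), c(0, 0))
  expect_equal(w$idf, c(both = 0, rare = log10(2)))
  # linearity in tf: doubling a count doubles its weight
  w2 <- tfidf(build_dfm(toy_docs(list(c("rare", "rare", "both"), "both"))))
  expect_equal(w2$weights["d1", "rare"], 2 * log10(2), tolerance = 1e-12)
})

test_that("tfidf sparsity matches the counts except all-document columns", {
  gen <- generate_corpus(small_cfg(n = 30, seed = 19))
  dfm <- build_dfm(preprocess_letters(gen$corpus))
  w <- tfidf(dfm)
  df <- Matrix::colSums(dfm != 0)
  full <- df == nrow(dfm)
  expect_equal(as.matrix(w$weights != 0)[, !full],
               as.matrix(dfm != 0)[, !full])
  if (any(full)) expect_true(all(w$weights[, full] == 0))
})

test_that("preranking keeps the k largest TF-IDF mass features, ties lexicographic", {
  W <- Matrix::sparseMatrix(i = c(1, 1, 1), j = 1:3, x = c(5, 1, 3),
                            dimnames = list("d1", c("f1", "f2", "f3")))
  wd <- structure(list(weights = W, idf = c(f1 = 1, f2 = 1, f3 = 1),
                       n_docs = 1), class = "weighted_dfm")
  expect_equal(prerank(wd, 2), c("f1", "f3"))
  expect_equal(prerank(wd, 99), c("f1", "f3", "f2"))
})

test_that("RFE keeps a class-pure feature over an uninformative one", {
  set.seed(42)
  # 20-doc toy: "pure" occurs only in epilepsy docs; "flat" everywhere
  labels <- rep(c("epilepsy", "no_epilepsy"), each = 10)
  feats <- lapply(seq_along(labels), function(i) {
    c(rep("flat", 3), if (labels[i] == "epilepsy") "pure" else "other",
      sample(letters[1:6], 2))
  })
  wd <- tfidf(build_dfm(toy_docs(feats)))
  sel <- rfe_select(wd, labels,
                    feature_selection_config(prerank_k = 10, final_k = 3,
                                             seed = 1))
  expect_true("pure" %in% sel$feature)
  imp <- stats::setNames(sel$importance, sel$feature)
  if ("flat" %in% sel$feature) expect_gt(imp[["pure"]], imp[["flat"]])
})

test_that("RFE with final_k = available returns the full set ranked by importance", {
  labels <- rep(c("epilepsy", "no_epilepsy"), each = 5)
  feats <- lapply(seq_along(labels), function(i)
    c("x", if (labels[i] == "epilepsy") "e" else "n"))
  wd <- tfidf(build_dfm(toy_docs(feats)))
  sel <- rfe_select(wd, labels,
                    feature_selection_config(prerank_k = 3, final_k = 3, seed = 2))
  expect_setequal(sel$feature, c("x", "e", "n"))
  expect_equal(sel$importance, sort(sel$importance, decreasing = TRUE))
  expect_error(rfe_select(wd, rep("epilepsy", 10),
                          feature_selection_config(prerank_k = 3, final_k = 2)),
               "both classes")
})

test_that("RFE is deterministic under a fixed seed and invariant to document order", {
  gen <- generate_corpus(small_cfg(n = 80, seed = 23))
  corp <- gen$corpus[gen$corpus$final_dx %in% c("epilepsy", "no_epilepsy"), ]
  wd <- tfidf(build_dfm(preprocess_letters(corp)))
  fs <- feature_selection_config(prerank_k = 200, final_k = 30, seed = 5)
  pre <- prerank(wd, fs$prerank_k)
  sel1 <- rfe_select(epiletter:::restrict_weighted(wd, pre), corp$final_dx, fs)
  sel2 <- rfe_select(epiletter:::restrict_weighted(wd, pre), corp$final_dx, fs)
  expect_identical(sel1, sel2)
  perm <- sample(nrow(corp))
  wd_p <- tfidf(build_dfm(preprocess_letters(corp[perm, ])))
  sel3 <- rfe_select(epiletter:::restrict_weighted(wd_p, pre),
                     corp$final_dx[perm], fs)
  expect_equal(sel1$feature, sel3$feature)
})

test_that("projection uses training idf on selected features and ignores unseen features", {
  train <- toy_docs(list(c("a", "b"), c("a", "c")))
  wd <- tfidf(build_dfm(train))
  sel <- c("a", "b")
  # unseen-only test doc projects to an all-zero row
  test1 <- toy_docs(list(c("zz", "qq")), ids = "t1")
  expect_equal(unname(as.matrix(project_docs(test1, sel, wd$idf)$weights)),
               matrix(0, 1, 2))
  # a test doc identical to a training doc reproduces its weight row
  test2 <- toy_docs(list(c("a", "b")), ids = "t2")
  expect_equal(unname(as.matrix(project_docs(test2, sel, wd$idf)$weights)),
               unname(as.matrix(wd$weights[1, sel, drop = FALSE])))
  expect_error(project_docs(test2, character(), wd$idf), "empty selected")
})

test_that("top features rank by class-favouring log-likelihood ratio and swap with labels", {
  feats <- list(c("drooled", "fever"), c("drooled"), c("dizzy"), c("dizzy", "fever"))
  labels <- c("epilepsy", "epilepsy", "no_epilepsy", "no_epilepsy")
  wd <- tfidf(build_dfm(toy_docs(feats)))
  m <- fit_nb(wd, labels, alpha = 0.5)
  top <- top_features_per_class(m, m = 2)
  expect_equal(top$epilepsy$feature[1], "drooled")
  expect_equal(top$no_epilepsy$feature[1], "dizzy")
  # symmetric toy: swapping class labels swaps the lists
  m2 <- fit_nb(wd, c("no_epilepsy", "no_epilepsy", "epilepsy", "epilepsy"),
               alpha = 0.5)
  top2 <- top_features_per_class(m2, m = 2)
  expect_equal(top2$epilepsy$feature, top$no_epilepsy$feature)
  expect_equal(top2$no_epilepsy$feature, top$epilepsy$feature)
  empty <- top_features_per_class(m, m = 0)
  expect_equal(nrow(empty$epilepsy), 0L)
})
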