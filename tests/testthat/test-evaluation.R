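test_that("stratified splitting hits exact per-stratum proportions and is seeded", {
  corp <- make_letters(rep("een twee drie vier vijf", 100),
                       final = rep(c("epilepsy", "no_epilepsy"), c(40, 60)),
                       ids = sprintf("L%03d", 1:100))
  sp <- stratified_split(corp, 0.2, seed = 3)
  test <- corp[corp$id %in% sp$test_ids, ]
  expect_equal(sum(test$final_dx == "epilepsy"), 8L)
  expect_equal(sum(test$final_dx == "no_epilepsy"), 12L)
  expect_identical(stratified_split(corp, 0.2, seed = 3)$test_ids, sp$test_ids)
  expect_setequal(c(sp$train_ids, sp$test_ids), corp$id)
  # a stratum below 2 letters goes to training with a warning
  tiny <- make_letters(rep("a b c", 3),
                       final = c("epilepsy", "no_epilepsy", "no_epilepsy"))
  expect_warning(sp2 <- stratified_split(tiny, 0.5, seed = 1), "fewer than 2")
  expect_true("T001" %in% sp2$train_ids)
})

test_that("the Analysis-B test set is exactly the initially-unclear definitive letters", {
  corp <- make_letters(rep("a b c", 3),
                       final = c("epilepsy", "unclear", "epilepsy"),
                       initial = c("unclear", "unclear", "epilepsy"))
  expect_equal(analysis_b_testset(corp), "T001")
  none <- make_letters("a b", final = "epilepsy", initial = "epilepsy")
  expect_warning(ids <- analysis_b_testset(none), "no initially-unclear")
  expect_length(ids, 0)
})

test_that("confusion counts partition prediction/truth pairs", {
  truth <- rep(c("epilepsy", "no_epilepsy"), c(10, 20))
  perfect <- confusion(truth, truth)
  expect_equal(unclass(perfect)[c("tp", "fp", "fn", "tn")],
               list(tp = 10L, fp = 0L, fn = 0L, tn = 20L))
  allpos <- confusion(rep("epilepsy", 30), truth)
  expect_equal(unclass(allpos)[c("tp", "fp", "fn", "tn")],
               list(tp = 10L, fp = 20L, fn = 0L, tn = 0L))
  cm <- confusion(tp = 40, tn = 176, fp = 62, fn = 15)
  expect_equal(cm$n_total, 293L)
  expect_error(confusion(c("epilepsy"), truth), "equal length")
  expect_error(confusion(tp = 1, tn = 1, fp = 0, fn = 0, n_total = 1),
               "n_total")
})

test_that("metrics use each proportion's own denominator with exact CIs", {
  cm <- confusion(tp = 62, tn = 153, fp = 40, fn = 30, n_total = 293)
  m <- compute_metrics(cm)
  acc <- m[m$metric == "accuracy", ]
  expect_equal(acc$estimate, 215 / 293, tolerance = 1e-12)
  expect_equal(round(acc$estimate, 2), 0.73)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(sens$estimate, 62 / 92, tolerance = 1e-12)
  perfect <- compute_metrics(confusion(tp = 10, tn = 20, fp = 0, fn = 0))
  expect_true(all(perfect$estimate == 1))
  # exact binomial CI oracle at x = 1, n = 2
  half <- compute_metrics(confusion(tp = 1, fn = 1, fp = 0, tn = 0))
  s <- half[half$metric == "sensitivity", ]
  expect_equal(s$estimate, 0.5)
  expect_equal(c(s$conf_low, s$conf_high), c(0.0126, 0.9874), tolerance = 1e-4)
  expect_error(compute_metrics(confusion(tp = 0, fp = 0, fn = 0, tn = 0)),
               "n_total = 0")
})

test_that("zero-denominator metrics are flagged undefined, never silently 0", {
  cm <- confusion(rep("no_epilepsy", 5), rep("no_epilepsy", 5))
  m <- compute_metrics(cm)
  expect_false(m$defined[m$metric == "ppv"])
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_false(m$defined[m$metric == "sensitivity"])
  expect_true(m$defined[m$metric == "accuracy"])
})

test_that("metric identities and CI containment hold over random confusion matrices", {
  set.seed(14)
  for (i in 1:12) {
    cm <- confusion(tp = sample(0:40, 1), fp = sample(0:40, 1),
                    fn = sample(0:40, 1), tn = sample(1:40, 1))
    m <- compute_metrics(cm)
    prev <- (cm$tp + cm$fn) / cm$n_total
    est <- stats::setNames(m$estimate, m$metric)
    if (all(m$defined[m$metric %in% c("sensitivity", "specificity")])) {
      expect_equal(est[["accuracy"]],
                   est[["sensitivity"]] * prev + est[["specificity"]] * (1 - prev),
                   tolerance = 1e-12)
    }
    ok <- m$defined
    expect_true(all(m$conf_low[ok] <= m$estimate[ok] + 1e-12))
    expect_true(all(m$conf_high[ok] >= m$estimate[ok] - 1e-12))
    # exact CI endpoints at the boundaries
    if (any(ok & m$x == 0)) expect_true(all(m$conf_low[ok & m$x == 0] == 0))
    if (any(ok & m$x == m$n)) expect_true(all(m$conf_high[ok & m$x == m$n] == 1))
  }
})

test_that("McNemar matches its closed form, its symmetry, and stats::mcnemar.test", {
  c1 <- c(rep(TRUE, 5), rep(FALSE, 10), rep(TRUE, 20))
  c2 <- c(rep(FALSE, 5), rep(TRUE, 10), rep(TRUE, 20))
  r <- mcnemar_compare(c1, c2, correction = TRUE)
  expect_equal(r$b, 5L)
  expect_equal(r$c, 10L)
  expect_equal(r$chi2, 16 / 15, tolerance = 1e-9)
  expect_equal(r$p, 0.3017, tolerance = 1e-4)
  # b = c: uncorrected statistic 0, p = 1
  req <- mcnemar_compare(c(TRUE, FALSE), c(FALSE, TRUE), correction = FALSE)
  expect_equal(req$chi2, 0)
  expect_equal(req$p, 1)
  # identical models: no discordant pairs
  same <- mcnemar_compare(c1, c1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # symmetry under swapping the two models
  swapped <- mcnemar_compare(c2, c1)
  expect_equal(swapped$chi2, r$chi2)
  expect_equal(swapped$p, r$p)
  expect_error(mcnemar_compare(c1, c2[-1]), "equal length")
  # independent implementation: stats::mcnemar.test on the paired table
  tab <- table(factor(c1, c(FALSE, TRUE)), factor(c2, c(FALSE, TRUE)))
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, unname(ref$p.value), tolerance = 1e-12)
})

test_that("a signal-free corpus yields majority-rate accuracy end to end", {
  flat_vs <- vocab_spec(
    epilepsy_signal = tibble::tibble(item = "kwijlde", multiplier = 1),
    control_signal = tibble::tibble(item = "flauwvallen", multiplier = 1))
  cfg <- small_cfg(n = 400, seed = 29, vocab = flat_vs)
  corp <- generate_corpus(cfg)$corpus
  rep_a <- run_analysis_a(corp, seed = 1,
                          fs = feature_selection_config(prerank_k = 500,
                                                        final_k = 60))
  maj <- with(rep_a$arms$nb, (confusion$tn + confusion$fp) / confusion$n_total)
  for (arm in names(rep_a$arms)) {
    acc <- rep_a$arms[[arm]]$accuracy
    expect_lt(abs(acc - maj),
              3 * sqrt(maj * (1 - maj) / rep_a$n_test) + 1e-9)
  }
})

test_that("Analysis B trains on letters disjoint from its test set and warns when empty", {
  cfg <- small_cfg(n = 300, seed = 33)
  corp <- generate_corpus(cfg)$corpus
  rep_b <- run_analysis_b(corp, seed = 2, arms = "nb",
                          fs = feature_selection_config(prerank_k = 400,
                                                        final_k = 50))
  expect_length(intersect(rep_b$split$train_ids, rep_b$split$test_ids), 0)
  expect_true(rep_b$test_ids_disjoint_from_training)
  expect_setequal(rep_b$split$test_ids,
                  analysis_b_testset(corp[corp$final_dx %in%
                                            c("epilepsy", "no_epilepsy"), ]))
  # no initially-unclear letters at all
  clear <- corp[corp$initial_dx != "unclear" &
                  corp$final_dx %in% c("epilepsy", "no_epilepsy"), ]
  warns <- capture_warnings(
    run_analysis_b(clear, seed = 2, arms = "nb",
                   fs = feature_selection_config(prerank_k = 400,
                                                 final_k = 50)))
  expect_true(any(grepl("no initially-unclear", warns)))
  expect_true(any(grepl("empty test set", warns)))
})
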