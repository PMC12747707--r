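test_that("identical config and seed give byte-identical corpora", {
  cfg <- small_cfg(n = 60, seed = 11)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(tibble::as_tibble(a$corpus), tibble::as_tibble(b$corpus))
  expect_identical(a$truth$letters, b$truth$letters)
})

test_that("marginal class, site and stratum fractions match the configuration at n = 10000", {
  cfg <- small_cfg(n = 10000, seed = 5)
  corp <- generate_corpus(cfg)$corpus
  n <- nrow(corp)
  for (cl in names(cfg$final_dx_props)) {
    p <- cfg$final_dx_props[[cl]]
    expect_lt(abs(mean(corp$final_dx == cl) - p), 3 * sqrt(p * (1 - p) / n))
  }
  p_site <- cfg$site_props[["site_A"]]
  expect_lt(abs(mean(corp$site == "site_A") - p_site),
            3 * sqrt(p_site * (1 - p_site) / n))
  p_iu <- cfg$p_initial_unclear
  expect_lt(abs(mean(corp$initial_dx == "unclear") - p_iu),
            3 * sqrt(p_iu * (1 - p_iu) / n))
  # final-unclear letters are always initially unclear
  expect_true(all(corp$initial_dx[corp$final_dx == "unclear"] == "unclear"))
})

test_that("a planted token at multiplier 5 occurs ~5x more often in its class", {
  vs <- vocab_spec(
    epilepsy_signal = tibble::tibble(item = "kwijlde", multiplier = 5),
    control_signal = tibble::tibble(item = "flauwvallen", multiplier = 5),
    signal_base_rate = 2e-3)
  cfg <- small_cfg(n = 2000, seed = 13, vocab = vs, p_initial_unclear = 0,
                   final_dx_props = c(epilepsy = 0.5, no_epilepsy = 0.5,
                                      unclear = 0))
  gen <- generate_corpus(cfg)
  counts <- vapply(gen$truth$letters$signal_counts, function(x)
    if ("kwijlde" %in% names(x)) x[["kwijlde"]] else 0, numeric(1))
  rate_e <- mean(counts[gen$corpus$final_dx == "epilepsy"])
  rate_n <- mean(counts[gen$corpus$final_dx == "no_epilepsy"])
  expect_lt(abs(rate_e / rate_n - 5) / 5, 0.2)
})

test_that("recorded ground truth reproduces the exact generative log-likelihood ratio", {
  cfg <- small_cfg(n = 40, seed = 3)
  gen <- generate_corpus(cfg)
  pool <- gen$truth$params
  items <- pool$items
  sig <- items$type %in% c("signal_epilepsy", "signal_control")
  lt <- gen$truth$letters
  for (i in seq_len(nrow(lt))) {
    stratum <- if (lt$initial_dx[i] == "unclear") "unclear" else "clear"
    site <- gen$corpus$site[gen$corpus$id == lt$id[i]]
    tab <- pool$tables[[paste(site, stratum, sep = ".")]]
    lr <- log(tab$epilepsy) - log(tab$no_epilepsy)
    cnt <- lt$signal_counts[[i]]
    n_sig <- sum(cnt)
    # non-signal items share one common likelihood ratio (the
    # normalization constant); signal items carry their own
    recomputed <- sum(cnt * lr[sig][match(names(cnt), items$item[sig])]) +
      (lt$n_items[i] - n_sig) * lr[which(!sig)[1]]
    expect_equal(recomputed, lt$loglik_epilepsy[i] - lt$loglik_no_epilepsy[i],
                 tolerance = 1e-9)
  }
})

test_that("the Bayes oracle degenerates correctly without signal", {
  flat_vs <- vocab_spec(
    epilepsy_signal = tibble::tibble(item = "kwijlde", multiplier = 1),
    control_signal = tibble::tibble(item = "flauwvallen", multiplier = 1))
  balanced <- small_cfg(n = 10, seed = 2, vocab = flat_vs,
                        final_dx_props = c(epilepsy = 0.5, no_epilepsy = 0.5,
                                           unclear = 0),
                        p_initial_unclear = 0)
  orc <- oracle_bayes_accuracy(balanced, n_mc = 2000, seed = 21)
  expect_lt(abs(orc$accuracy - 0.5), 3 * sqrt(0.25 / 2000))

  skewed <- small_cfg(n = 10, seed = 2, vocab = flat_vs,
                      final_dx_props = c(epilepsy = 0.35, no_epilepsy = 0.65,
                                         unclear = 0),
                      p_initial_unclear = 0)
  orc2 <- oracle_bayes_accuracy(skewed, n_mc = 2000, seed = 22)
  expect_lt(abs(orc2$accuracy - 0.65), 3 * sqrt(0.65 * 0.35 / 2000))

  expect_error(oracle_bayes_accuracy(balanced, n_mc = 50), "at least 100")
})

test_that("length statistics are exact on hand-counted corpora", {
  corp <- make_letters(c(paste(rep("a", 10), collapse = " "),
                         paste(rep("b", 20), collapse = " "),
                         paste(rep("c", 30), collapse = " ")))
  expect_equal(length_statistics(corp),
               list(min = 10L, max = 30L, median = 20, mean = 20))
  one <- make_letters(paste(rep("a", 7), collapse = " "))
  expect_equal(length_statistics(one),
               list(min = 7L, max = 7L, median = 7, mean = 7))
  expect_error(length_statistics(make_letters(character(0))), "empty corpus")
})

test_that("infeasible or inconsistent configurations are rejected", {
  expect_error(synth_config(length_model = list(min_words = 63, max_words = 100,
                                                median_target = 400,
                                                mean_target = 414)),
               "infeasible length model")
  expect_error(synth_config(final_dx_props = c(epilepsy = 0.5,
                                               no_epilepsy = 0.4,
                                               unclear = 0.2)),
               "sum to 1")
  bad_vs <- vocab_spec(epilepsy_signal = tibble::tibble(item = "geen",
                                                        multiplier = 3))
  expect_error(synth_config(vocab = bad_vs), "disjoint from the stopword")
})

test_that("synthetic configurations round-trip through YAML", {
  cfg <- small_cfg(n = 25, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$n_letters, cfg$n_letters)
  expect_equal(back$length_model, cfg$length_model)
  expect_equal(back$vocab$epilepsy_signal, cfg$vocab$epilepsy_signal)
  expect_identical(tibble::as_tibble(generate_corpus(back)$corpus),
                   tibble::as_tibble(generate_corpus(cfg)$corpus))
})
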