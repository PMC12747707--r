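#' Simulate a letter corpus to disk
#'
#' Generates a synthetic corpus and writes `corpus.jsonl`,
#' `ground_truth.jsonl` and `synth_config.yaml` into `dir`. Repeating
#' the call with the same configuration (including its seed) rewrites
#' identical files.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated `corpus`, `truth` and
#'   file `paths`.
#' @export
simulate_letters <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_corpus(config)
  paths <- list(corpus = file.path(dir, "corpus.jsonl"),
                truth = file.path(dir, "ground_truth.jsonl"),
                config = file.path(dir, "synth_config.yaml"))
  write_corpus(gen$corpus, paths$corpus, format = "jsonl")
  write_ground_truth(gen$truth, paths$truth)
  write_synth_config(config, paths$config)
  invisible(list(corpus = gen$corpus, truth = gen$truth, paths = paths))
}

#' Run the full evaluation (Analyses A and B, both arms)
#'
#' End-to-end orchestration under a single master seed: embeds the
#' corpus once with the offline provider (embedding is a fixed
#' per-document map, so sharing it across analyses leaks nothing),
#' runs the requested analyses and arms, and optionally writes JSON
#' reports plus a consolidated Markdown table. With the offline
#' embedding provider the entire run is deterministic: the same corpus
#' and master seed reproduce every number bit-for-bit.
#'
#' @param corpus A `letter_corpus`.
#' @param analyses `"A"`, `"B"` or both.
#' @param arms `"nb"`, `"embed"` or both.
#' @param seed Master seed propagated to every stage.
#' @param out_dir Optional directory for report files.
#' @param provider Embedding provider (default [hash_embedder()]).
#' @param ... Passed to [run_analysis_a()] / [run_analysis_b()]
#'   (`min_words`, `pp`, `fs`, `alpha`, `alpha_grid`, `control`).
#' @return Named list of `analysis_report`s.
#' @export
run_analyses <- function(corpus, analyses = c("A", "B"),
                         arms = c("nb", "embed"), seed = 1L,
                         out_dir = NULL, provider = hash_embedder(), ...) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  arms <- match.arg(arms, several.ok = TRUE)
  embeddings <- if ("embed" %in% arms) {
    embed_letters(corpus$anamnesis_text, provider, ids = corpus$id)
  } else NULL
  reports <- list()
  if ("A" %in% analyses) {
    reports$A <- run_analysis_a(corpus, seed = child_seed(seed, 1L),
                                arms = arms, provider = provider,
                                embeddings = embeddings, ...)
  }
  if ("B" %in% analyses) {
    reports$B <- run_analysis_b(corpus, seed = child_seed(seed, 2L),
                                arms = arms, provider = provider,
                                embeddings = embeddings, ...)
  }
  if (!is.null(out_dir)) {
    write_reports(reports, out_dir)
  }
  reports
}

report_to_list <- function(report) {
  arms <- lapply(report$arms, function(a) {
    list(confusion = unclass(a$confusion),
         metrics = as.data.frame(a$metrics),
         accuracy = a$accuracy,
         accuracy_by_stratum = as.list(a$accuracy_by_stratum))
  })
  list(analysis = report$analysis, n_train = report$n_train,
       n_test = report$n_test,
       excluded = as.data.frame(report$excluded),
       arms = arms,
       mcnemar = if (!is.null(report$mcnemar)) unclass(report$mcnemar),
       top_features = if (!is.null(report$top_features)) {
         lapply(unclass(report$top_features), as.data.frame)
       },
       settings = report$settings)
}

write_reports <- function(reports, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(reports)) {
    jsonlite::write_json(report_to_list(reports[[nm]]),
                         file.path(out_dir, paste0("analysis_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    split <- reports[[nm]]$split
    readr::write_csv(tibble::tibble(
      id = c(split$train_ids, split$test_ids),
      set = rep(c("train", "test"),
                c(length(split$train_ids), length(split$test_ids)))),
      file.path(out_dir, paste0("split_", nm, ".csv")), progress = FALSE)
  }
  tab <- report_table(reports)
  writeLines(format_report_markdown(tab),
             file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' Consolidated performance table
#'
#' One row per analysis x model with the five diagnostic metrics, each
#' formatted as `estimate (low-high)` from its 95% confidence interval.
#'
#' @param reports A list of `analysis_report`s (as returned by
#'   [run_analyses()]) or a single report.
#' @return A tibble with columns `analysis`, `model`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "analysis_report")) reports <- list(reports)
  rows <- list()
  for (rep in reports) {
    for (arm in names(rep$arms)) {
      m <- rep$arms[[arm]]$metrics
      fmt <- vapply(c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
                    function(metric) {
                      r <- m[m$metric == metric, ]
                      if (!isTRUE(r$defined)) return("undefined")
                      sprintf("%.2f (%.2f-%.2f)", r$estimate, r$conf_low,
                              r$conf_high)
                    }, character(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analysis = rep$analysis,
        model = c(nb = "NB", embed = "Embedding")[[arm]],
        accuracy = fmt[["accuracy"]], sensitivity = fmt[["sensitivity"]],
        specificity = fmt[["specificity"]], ppv = fmt[["ppv"]],
        npv = fmt[["npv"]])
    }
  }
  do.call(rbind, rows)
}

format_report_markdown <- function(tab) {
  header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("| ", paste(unlist(tab[i, ]), collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}
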