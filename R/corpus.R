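#' Letter corpora
#'
#' A letter corpus is a tibble with one row per anamnesis letter and the
#' seven required columns `id`, `site`, `anamnesis_text`, `sex`,
#' `age_years`, `initial_dx`, `final_dx`. Diagnoses take one of three
#' values: `"epilepsy"`, `"no_epilepsy"` or `"unclear"`. The final
#' diagnosis (consensus after up to two years of follow-up) is the gold
#' standard label; the initial diagnosis is used only to stratify the
#' analyses. Validation rejects, rather than coerces, malformed rows.
#'
#' @param letters A data frame with the seven required columns.
#' @param provenance Free-text provenance tag (e.g. `"synthetic seed=1"`).
#' @return A validated `letter_corpus` tibble.
#' @export
as_letter_corpus <- function(letters, provenance = "unspecified") {
  df <- tibble::as_tibble(letters)
  validate_letters(df)
  df <- df[, CORPUS_COLUMNS]
  df$id <- as.character(df$id)
  df$age_years <- as.numeric(df$age_years)
  structure(df,
            class = c("letter_corpus", class(tibble::tibble())),
            provenance = provenance)
}

validate_letters <- function(df) {
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("corpus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("corpus validation error: duplicate id(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  empty <- df$id[is.na(df$anamnesis_text) | !nzchar(trimws(df$anamnesis_text))]
  if (length(empty)) {
    stop("corpus validation error: empty anamnesis_text for id(s) ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  check_enum(df, "site", SITE_LEVELS)
  check_enum(df, "sex", SEX_LEVELS)
  check_enum(df, "initial_dx", DX_LEVELS)
  check_enum(df, "final_dx", DX_LEVELS)
  if (any(is.na(df$age_years)) || any(df$age_years < 0)) {
    stop("corpus validation error: age_years must be non-negative", call. = FALSE)
  }
  invisible(df)
}

check_enum <- function(df, column, levels) {
  bad <- !(df[[column]] %in% levels)
  if (any(bad)) {
    stop("corpus validation error: invalid ", column, " value(s) ",
         paste(unique(df[[column]][bad]), collapse = ", "),
         " for id(s) ", paste(df$id[bad], collapse = ", "),
         "; allowed: ", paste(levels, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.letter_corpus <- function(x, ...) {
  cat("<letter_corpus> ", nrow(x), " letters (provenance: ",
      attr(x, "provenance") %||% "unspecified", ")\n", sep = "")
  NextMethod()
}

#' Read a letter corpus from disk
#'
#' Reads JSONL (one letter object per line, the canonical format because
#' letters contain commas and newlines) or CSV with the seven required
#' columns. Rows with invalid enum values are rejected with an error, not
#' coerced.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @param provenance Provenance tag attached to the corpus.
#' @return A `letter_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        provenance = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    con <- file(path, encoding = "UTF-8")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      empty_corpus_frame()
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(),
      site = readr::col_character(),
      anamnesis_text = readr::col_character(),
      sex = readr::col_character(),
      age_years = readr::col_double(),
      initial_dx = readr::col_character(),
      final_dx = readr::col_character()
    ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
  }
  as_letter_corpus(df, provenance = provenance %||% paste0("file:", basename(path)))
}

empty_corpus_frame <- function() {
  tibble::tibble(id = character(), site = character(),
                 anamnesis_text = character(), sex = character(),
                 age_years = numeric(), initial_dx = character(),
                 final_dx = character())
}

#' Write a letter corpus to disk
#'
#' The written file round-trips: reading it back yields a corpus equal
#' field-for-field to the input (UTF-8 throughout, so Dutch diacritics
#' survive).
#'
#' @param corpus A `letter_corpus` (or validatable data frame).
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  corpus <- as_letter_corpus(corpus, provenance = attr(corpus, "provenance") %||% "unspecified")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, CORPUS_COLUMNS]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con, useBytes = FALSE)
  } else {
    readr::write_csv(tibble::as_tibble(corpus)[, CORPUS_COLUMNS], path, progress = FALSE)
  }
  invisible(path)
}

#' Exclude succinct letters
#'
#' Drops letters whose anamnesis text has fewer than `min_words`
#' whitespace-delimited words, mirroring the study's exclusion of
#' single-sentence letters from model training. The boundary is
#' inclusive: a letter with exactly `min_words` words is retained. The
#' default of 20 words sits well below the observed minimum letter length
#' (63 words), so it only fires on genuinely succinct letters.
#'
#' @param corpus A `letter_corpus`.
#' @param min_words Minimum word count to retain (default 20).
#' @return A list with `corpus` (the retained letters) and `exclusions`,
#'   a tibble of `(id, word_count)` for every dropped letter.
#' @export
exclude_short_letters <- function(corpus, min_words = 20L) {
  stopifnot(min_words >= 1)
  wc <- word_count(corpus$anamnesis_text)
  keep <- wc >= min_words
  exclusions <- tibble::tibble(id = corpus$id[!keep], word_count = wc[!keep])
  kept <- corpus[keep, , drop = FALSE]
  attr(kept, "provenance") <- attr(corpus, "provenance")
  class(kept) <- class(corpus)
  list(corpus = kept, exclusions = exclusions)
}
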