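# Shared enum levels. 'epilepsy' is always the positive class.
DX_LEVELS <- c("epilepsy", "no_epilepsy", "unclear")
BINARY_DX <- c("epilepsy", "no_epilepsy")
SITE_LEVELS <- c("site_A", "site_B")
SEX_LEVELS <- c("male", "female")

CORPUS_COLUMNS <- c("id", "site", "anamnesis_text", "sex", "age_years",
                    "initial_dx", "final_dx")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage sub-seeds derived from one master seed; kept
# below 2^31 - 1 so they are always valid R integer seeds.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * as.numeric(k)) %% 2147483647)
}

#' Whitespace word counts
#'
#' Counts whitespace-delimited words, the length convention used for the
#' short-letter exclusion rule and the corpus length statistics.
#'
#' @param text Character vector.
#' @return Integer vector of word counts (0 for empty strings).
#' @export
word_count <- function(text) {
  text <- trimws(text)
  n <- lengths(strsplit(text, "[[:space:]]+"))
  n[!nzchar(text)] <- 0L
  as.integer(n)
}
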