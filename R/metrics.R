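#' Confusion matrix for the binary epilepsy task
#'
#' Positive class is always `epilepsy`. `n_total` defaults to
#' `tp + fp + fn + tn` but may be overridden, which exists solely to
#' reproduce published accuracy figures whose printed counts do not sum
#' to the stated test size; the override only affects the accuracy
#' denominator.
#'
#' @param predicted,truth Aligned label vectors, or pass counts directly
#'   via `tp`, `fp`, `fn`, `tn`.
#' @param tp,fp,fn,tn Direct counts (used when `predicted` is missing).
#' @param n_total Optional denominator override (must be >= the count
#'   sum).
#' @return A `confusion_matrix` list.
#' @export
confusion <- function(predicted = NULL, truth = NULL,
                      tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                      n_total = NULL) {
  if (!is.null(predicted)) {
    if (length(predicted) != length(truth)) {
      stop("predicted and truth must have equal length", call. = FALSE)
    }
    predicted <- as.character(predicted)
    truth <- as.character(truth)
    stopifnot(all(predicted %in% BINARY_DX), all(truth %in% BINARY_DX))
    tp <- sum(predicted == "epilepsy" & truth == "epilepsy")
    fp <- sum(predicted == "epilepsy" & truth == "no_epilepsy")
    fn <- sum(predicted == "no_epilepsy" & truth == "epilepsy")
    tn <- sum(predicted == "no_epilepsy" & truth == "no_epilepsy")
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  n_total <- n_total %||% total
  if (n_total < total) stop("n_total cannot be below tp+fp+fn+tn", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_total = as.integer(n_total)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = epilepsy)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("epilepsy", "no_epilepsy"),
                              truth = c("epilepsy", "no_epilepsy")))
  print(m)
  cat("n_total =", x$n_total, "\n")
  invisible(x)
}

ci_prop <- function(x, n, method, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
  } else if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    mid <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, mid - half), min(1, mid + half))
  } else {  # wald
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- x / n
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  }
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Accuracy, sensitivity (true positive rate), specificity (true
#' negative rate), PPV and NPV, each with a 95% confidence interval
#' computed on the metric's own binomial denominator. The default CI is
#' the exact Clopper-Pearson interval; Wilson and Wald are available. A
#' metric whose denominator is zero is reported as undefined
#' (`defined = FALSE`, estimate `NA`), never silently 0.
#'
#' @param cm A [confusion()] matrix.
#' @param ci_method `"clopper-pearson"` (default), `"wilson"` or
#'   `"wald"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `metrics_report` tibble with columns `metric`, `x`, `n`,
#'   `estimate`, `conf_low`, `conf_high`, `defined`.
#' @export
compute_metrics <- function(cm, ci_method = c("clopper-pearson", "wilson", "wald"),
                            conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  if (cm$n_total == 0) stop("empty confusion matrix (n_total = 0)", call. = FALSE)
  defs <- list(
    accuracy    = c(cm$tp + cm$tn, cm$n_total),
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn)
  )
  rows <- lapply(names(defs), function(metric) {
    x <- defs[[metric]][1]; n <- defs[[metric]][2]
    if (n == 0) {
      tibble::tibble(metric = metric, x = x, n = n, estimate = NA_real_,
                     conf_low = NA_real_, conf_high = NA_real_,
                     defined = FALSE)
    } else {
      ci <- ci_prop(x, n, ci_method, conf_level)
      tibble::tibble(metric = metric, x = x, n = n, estimate = x / n,
                     conf_low = ci[1], conf_high = ci[2], defined = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("metrics_report", class(out)),
            ci_method = ci_method, conf_level = conf_level, cm = cm)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> (", attr(x, "ci_method"), " ",
      100 * attr(x, "conf_level"), "% CI)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$defined[i])) {
      cat(sprintf("  %-12s %.2f (%.2f-%.2f)  [%d/%d]\n", x$metric[i],
                  x$estimate[i], x$conf_low[i], x$conf_high[i], x$x[i], x$n[i]))
    } else {
      cat(sprintf("  %-12s undefined (zero denominator)\n", x$metric[i]))
    }
  }
  invisible(x)
}

#' McNemar's test for two paired classifiers
#'
#' Compares two models evaluated on the same test set through their
#' discordant correctness counts: `b` documents only model 1 got right,
#' `c` documents only model 2 got right. The statistic is
#' `(|b - c| - 1)^2 / (b + c)` with continuity correction (the default)
#' or `(b - c)^2 / (b + c)` without, referred to chi-square with 1
#' degree of freedom. With no discordant pairs the statistic is 0 and
#' p = 1. Both corrected and uncorrected statistics are reported.
#'
#' @param correct1,correct2 Logical vectors: per-document correctness of
#'   each model on the same test set.
#' @param correction Apply the continuity correction (default `TRUE`).
#' @return A `mcnemar_result` list with `b`, `c`, `chi2`, `df`, `p`,
#'   `correction`, plus `chi2_uncorrected` / `p_uncorrected`.
#' @export
mcnemar_compare <- function(correct1, correct2, correction = TRUE) {
  if (length(correct1) != length(correct2)) {
    stop("correctness vectors must have equal length", call. = FALSE)
  }
  correct1 <- as.logical(correct1)
  correct2 <- as.logical(correct2)
  b <- sum(correct1 & !correct2)
  c_ <- sum(!correct1 & correct2)
  stat <- function(corr) {
    if (b + c_ == 0) return(c(0, 1))
    num <- if (corr) (abs(b - c_) - 1)^2 else (b - c_)^2
    chi2 <- num / (b + c_)
    c(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  with_corr <- stat(TRUE)
  without <- stat(FALSE)
  chosen <- if (correction) with_corr else without
  structure(list(b = b, c = c_, chi2 = chosen[1], df = 1L, p = chosen[2],
                 correction = correction,
                 chi2_uncorrected = without[1], p_uncorrected = without[2],
                 chi2_corrected = with_corr[1], p_corrected = with_corr[2]),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf(paste0("<mcnemar_result> b = %d, c = %d; chi2 = %.4f, df = 1, ",
                     "p = %.4f (%s)\n  uncorrected: chi2 = %.4f, p = %.4f\n"),
              x$b, x$c, x$chi2, x$p,
              if (x$correction) "continuity-corrected" else "uncorrected",
              x$chi2_uncorrected, x$p_uncorrected))
  invisible(x)
}
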