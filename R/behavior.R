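#' Validate a behavioral dataset
#'
#' The behavioral table has one row per subject x word with columns
#' `subject_id`, `word_id`, `condition` (`"spontaneous"` for
#' once-presented words, `"forced"` for five-times-presented words),
#' `confidence` (recognition-memory confidence, 0-100) and `essay_len`
#' (essay character count; 0 when the word was not selected). An optional
#' `essay_tokens` list column holds pre-tokenized essays.
#'
#' @param data A data frame.
#' @return The data invisibly; errors describe the first violated rule.
#' @export
validate_behavior_data <- function(data) {
  need <- c("subject_id", "word_id", "condition", "confidence", "essay_len")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("behavioral data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("behavioral data is empty", call. = FALSE)
  if (!all(data$condition %in% c("spontaneous", "forced"))) {
    stop("condition must be 'spontaneous' or 'forced'", call. = FALSE)
  }
  if (any(!is.finite(data$confidence)) ||
      any(data$confidence < 0 | data$confidence > 100)) {
    stop("confidence must lie in [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(data$essay_len)) || any(data$essay_len < 0)) {
    stop("essay_len must be nonnegative", call. = FALSE)
  }
  dup <- duplicated(data[c("subject_id", "word_id")])
  if (any(dup)) stop("duplicated subject x word rows", call. = FALSE)
  invisible(data)
}

#' Normalize essay lengths within subjects
#'
#' Divides each essay length by the subject's total essay length, so that
#' the normalized lengths of every retained subject sum to 1 (words without
#' an essay stay at 0). This cancels between-subject differences in
#' baseline productivity. Subjects whose total length is 0 cannot be
#' normalized and are dropped with a warning.
#'
#' @param data A behavioral data frame (see [validate_behavior_data()]).
#' @return The data with an added `norm_len` column, excluded subjects
#'   removed. The ids of dropped subjects are in attribute
#'   `dropped_subjects`.
#' @export
normalize_lengths <- function(data) {
  validate_behavior_data(data)
  totals <- tapply(data$essay_len, data$subject_id, sum)
  bad <- names(totals)[totals <= 0]
  if (length(bad)) {
    warning(sprintf("dropping %d subject(s) with zero total essay length",
                    length(bad)))
    data <- data[!(data$subject_id %in% bad), , drop = FALSE]
  }
  if (!nrow(data)) stop("no subjects left after exclusion", call. = FALSE)
  tot <- tapply(data$essay_len, data$subject_id, sum)
  data$norm_len <- data$essay_len / as.numeric(tot[as.character(data$subject_id)])
  attr(data, "dropped_subjects") <- bad
  data
}

#' Confidence-band membership
#'
#' Band boundaries follow the analysis conventions exactly: `"analyzed"` is
#' `50 <= c <= 100` (scores below 50 express confidence of *absence* and
#' are excluded), `"lower"` is `50 <= c <= 75` (75 belongs to the lower
#' band), `"upper"` is `75 < c <= 100`, and `"certain"` is `c == 100`.
#'
#' @param confidence Numeric vector of ratings in \[0, 100\].
#' @param band One of `"analyzed"`, `"lower"`, `"upper"`, `"certain"`.
#' @return Logical vector.
#' @export
#' @examples
#' confidence_band(c(49, 50, 75, 76, 100), "lower")
confidence_band <- function(confidence,
                            band = c("analyzed", "lower", "upper",
                                     "certain")) {
  band <- match.arg(band)
  switch(band,
         analyzed = confidence >= 50 & confidence <= 100,
         lower = confidence >= 50 & confidence <= 75,
         upper = confidence > 75 & confidence <= 100,
         certain = confidence == 100)
}

#' Probability of superiority
#'
#' Nonparametric effect size for a two-group comparison: the proportion of
#' all cross-group pairs in which the sample from `a` exceeds the sample
#' from `b`; ties contribute one half. Equals `U_a / (n_a * n_b)` for the
#' mid-rank Mann-Whitney U statistic.
#'
#' @param a,b Numeric samples (both nonempty).
#' @return PS in \[0, 1\].
#' @export
#' @examples
#' probability_of_superiority(c(1, 3), c(2, 4))  # 0.25
probability_of_superiority <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty",
                                     call. = FALSE)
  gt <- outer(a, b, ">")
  eq <- outer(a, b, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(a) * length(b))
}

#' Two-group comparison with effect size and bootstrap CIs
#'
#' Wraps the standard tests used for the behavioral comparisons. The
#' Mann-Whitney U test (for clearly non-Gaussian data) reports the
#' probability of superiority ([probability_of_superiority()]) as its
#' effect size and percentile-bootstrap CIs of the group *medians*; the
#' independent t-test reports Cohen's d and CIs of the group *means*; the
#' paired t-test reports d_z (mean difference over the sd of differences)
#' and a CI of the mean difference.
#'
#' @param a,b Numeric samples. Interpreted so that the one-sided
#'   alternative `"greater"` means "a tends to exceed b".
#' @param test `"mann-whitney"`, `"t"` or `"paired-t"`.
#' @param alternative Passed to the underlying test; default `"greater"`
#'   (one-sided as in pre-registered directional hypotheses).
#' @param n_boot Bootstrap resamples for the CIs.
#' @param conf_level CI coverage.
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `group_comparison`: `statistic`, `p_value`,
#'   `effect_size`, `effect_name`, `n` (per group), `centers`, `ci` (per
#'   group, or of the difference for the paired test), `test`,
#'   `alternative`, `degenerate` (e.g. zero-variance paired differences).
#' @export
compare_groups <- function(a, b,
                           test = c("mann-whitney", "t", "paired-t"),
                           alternative = "greater",
                           n_boot = 10000L, conf_level = 0.95,
                           seed = NULL) {
  test <- match.arg(test)
  if (!is.null(seed)) set.seed(seed)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (test == "paired-t" && length(a) != length(b)) {
    stop("paired test requires equal-length samples", call. = FALSE)
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop(sprintf("insufficient group sizes (n_a = %d, n_b = %d)",
                 length(a), length(b)), call. = FALSE)
  }
  degenerate <- FALSE
  if (test == "mann-whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = alternative,
                                              exact = FALSE))
    es <- probability_of_superiority(a, b)
    es_name <- "PS"
    centers <- c(a = stats::median(a), b = stats::median(b))
    ci <- rbind(a = boot_ci(a, stats::median, n_boot, conf_level),
                b = boot_ci(b, stats::median, n_boot, conf_level))
  } else if (test == "t") {
    ht <- stats::t.test(a, b, alternative = alternative, var.equal = TRUE)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    es <- if (sp > 0) (mean(a) - mean(b)) / sp else NA_real_
    degenerate <- sp == 0
    es_name <- "d"
    centers <- c(a = mean(a), b = mean(b))
    ci <- rbind(a = boot_ci(a, mean, n_boot, conf_level),
                b = boot_ci(b, mean, n_boot, conf_level))
  } else {
    d <- a - b
    sdd <- stats::sd(d)
    if (sdd == 0) {
      # constant differences: no within-pair variability to test against
      degenerate <- TRUE
      ht <- list(statistic = c(t = NA_real_),
                 p.value = if (mean(d) == 0) 1 else NA_real_)
      es <- NA_real_
    } else {
      ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
      es <- mean(d) / sdd
    }
    es_name <- "d_z"
    centers <- c(difference = mean(d))
    ci <- rbind(difference = boot_ci(d, mean, n_boot, conf_level))
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 effect_size = unname(es), effect_name = es_name,
                 n = c(a = length(a), b = length(b)),
                 centers = centers, ci = ci, test = test,
                 alternative = alternative, degenerate = degenerate),
            class = "group_comparison")
}

boot_ci <- function(x, fun, n_boot, conf_level) {
  reps <- vapply(seq_len(n_boot),
                 function(i) fun(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - conf_level) / 2
  stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (alternative: %s)\n", x$test,
              x$alternative))
  cat(sprintf("  statistic = %.4g, p = %.4g, %s = %.3g, n = (%d, %d)%s\n",
              x$statistic, x$p_value, x$effect_name, x$effect_size,
              x$n[1], x$n[2],
              if (x$degenerate) " [degenerate]" else ""))
  for (i in seq_len(nrow(x$ci))) {
    cat(sprintf("  %s: center %.4g, CI [%.4g, %.4g]\n", rownames(x$ci)[i],
                x$centers[i], x$ci[i, 1], x$ci[i, 2]))
  }
  invisible(x)
}
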