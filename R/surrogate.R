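#' Dot-product shuffle surrogate test
#'
#' Tests whether, within subjects, essay lengths increase with
#' recognition-memory confidence. For every included subject the confidence
#' ratings and essay lengths of the analyzed words (`50 <= c <= 100`) are
#' each L2-unitized, and the subject contributes the dot product of the two
#' unit vectors; the observed statistic sums these over subjects, so its
#' theoretical maximum equals the number of subjects (all entries are
#' nonnegative, minimum 0). The null distribution is built by shuffling,
#' independently within each subject, the order of the components of the
#' length vector, and summing across subjects; the upper-tail p-value uses
#' the `(k + 1) / (n + 1)` correction.
#'
#' Subjects with fewer than two analyzed words or an all-zero length vector
#' cannot contribute a unit vector and are excluded (counted in
#' `n_excluded`).
#'
#' @param data A behavioral data frame (raw or normalized lengths — the
#'   statistic is invariant to positive rescaling within subjects).
#' @param n_surrogate Number of surrogate draws.
#' @param seed Optional integer seed.
#' @param words `"analyzed"` (default) restricts to the 50-100 confidence
#'   band; `"all"` uses every word.
#' @return Object of class `surrogate_result`: `observed_stat`,
#'   `null_samples`, `n_surrogate`, `p_value`, `theoretical_min`,
#'   `theoretical_max` (= number of included subjects), `n_subjects`,
#'   `n_excluded`.
#' @export
dot_product_surrogate_test <- function(data, n_surrogate = 1000L,
                                       seed = NULL,
                                       words = c("analyzed", "all")) {
  words <- match.arg(words)
  validate_behavior_data(data)
  if (!is.null(seed)) set.seed(seed)
  if (words == "analyzed") {
    data <- data[confidence_band(data$confidence, "analyzed"), ,
                 drop = FALSE]
  }
  split_s <- split(data, data$subject_id)
  obs <- 0
  null_sum <- numeric(n_surrogate)
  n_inc <- 0L
  n_exc <- 0L
  for (s in split_s) {
    cv <- s$confidence
    lv <- s$essay_len
    if (length(cv) < 2L || sum(lv^2) == 0 || sum(cv^2) == 0) {
      n_exc <- n_exc + 1L
      next
    }
    n_inc <- n_inc + 1L
    u <- cv / sqrt(sum(cv^2))
    x <- lv / sqrt(sum(lv^2))
    obs <- obs + sum(u * x)
    # one independent uniform shuffle of x per surrogate draw: ranking iid
    # uniform keys within each draw's block yields a uniform permutation
    n <- length(x)
    key <- order(rep(seq_len(n_surrogate), each = n),
                 stats::runif(n * n_surrogate))
    null_sum <- null_sum +
      drop(u %*% matrix(x[(key - 1L) %% n + 1L], n, n_surrogate))
  }
  if (n_inc == 0L) stop("no subjects qualify for the dot-product test",
                        call. = FALSE)
  new_surrogate_result(obs, null_sum, n_inc, n_exc)
}

#' Letter-reassignment surrogate test
#'
#' Tests whether, among words recognized with absolute certainty
#' (`confidence == 100`), spontaneously memorized (once-presented) words
#' yield longer essays than forcedly memorized (five-times-presented)
#' words. Per subject the essay lengths of the certain words are
#' renormalized to total 1 and the subject contributes the total normalized
#' length of its spontaneous certain words; the observed statistic sums
#' contributions over subjects (theoretical range 0 to the number of
#' subjects). Null draws reassign each subject's letters uniformly at
#' random over the *essays* written for that subject's certain words (a
#' uniform multinomial over those essays, so the spontaneous subset total
#' is binomial), renormalize, and sum across subjects; the upper-tail
#' p-value uses the `(k + 1) / (n + 1)` correction. Certain words without
#' an essay carry no letters and take no part in the reassignment.
#'
#' Included subjects need at least one certain word with a nonzero essay.
#' Subjects whose certain-word essays are all for spontaneous words
#' contribute exactly 1 to both the observed and every surrogate sum (no
#' competition), leaving the p-value unaffected.
#'
#' @param data A behavioral data frame with raw `essay_len` letter counts.
#' @param n_surrogate Number of surrogate draws.
#' @param seed Optional integer seed.
#' @return A `surrogate_result` (see [dot_product_surrogate_test()]).
#' @export
letter_reassignment_surrogate_test <- function(data, n_surrogate = 1000L,
                                               seed = NULL) {
  validate_behavior_data(data)
  if (!is.null(seed)) set.seed(seed)
  certain <- data[confidence_band(data$confidence, "certain"), ,
                  drop = FALSE]
  split_s <- split(certain, certain$subject_id, drop = TRUE)
  obs <- 0
  null_sum <- numeric(n_surrogate)
  n_inc <- 0L
  n_exc <- 0L
  for (s in split_s) {
    total <- sum(s$essay_len)
    if (total <= 0) {
      n_exc <- n_exc + 1L
      next
    }
    n_inc <- n_inc + 1L
    essayed <- s$essay_len > 0
    spont <- s$condition == "spontaneous"
    obs <- obs + sum(s$essay_len[spont]) / total
    k <- sum(essayed)
    m <- sum(spont & essayed)
    letters <- round(total)
    # uniform multinomial letter reassignment over the k certain-word
    # essays; the spontaneous-subset total is Binomial(letters, m / k)
    null_sum <- null_sum +
      stats::rbinom(n_surrogate, letters, m / k) / letters
  }
  if (n_inc == 0L) stop("no subjects qualify for the letter-reassignment test",
                        call. = FALSE)
  new_surrogate_result(obs, null_sum, n_inc, n_exc)
}

new_surrogate_result <- function(obs, null_samples, n_subjects, n_excluded) {
  p <- (1 + sum(null_samples >= obs)) / (length(null_samples) + 1)
  structure(list(observed_stat = obs, null_samples = null_samples,
                 n_surrogate = length(null_samples), p_value = p,
                 theoretical_min = 0, theoretical_max = n_subjects,
                 n_subjects = n_subjects, n_excluded = n_excluded),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> observed = %.4g (range [0, %d], n = %d subjects)\n",
              x$observed_stat, x$theoretical_max, x$n_subjects))
  cat(sprintf("  null: %d draws, mean %.4g; one-sided p = %.4g\n",
              x$n_surrogate, mean(x$null_samples), x$p_value))
  invisible(x)
}
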