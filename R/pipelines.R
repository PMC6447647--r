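# Per-subject mean of `col` over rows satisfying `keep`; named numeric.
subject_band_means <- function(data, keep, col = "norm_len") {
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(d[[col]], d$subject_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

# Mean essay-to-component similarity per subject over the rows in `d`
subject_semantic_means <- function(d, embedding, word_components) {
  scores <- vapply(seq_len(nrow(d)), function(i) {
    wc <- word_components[word_components$word_id == d$word_id[i], ]
    if (!nrow(wc)) return(NA_real_)
    es <- essay_similarity(embedding, d$essay_tokens[[i]],
                           wc$component_a[1], wc$component_b[1])
    if (es$defined) es$mean_similarity else NA_real_
  }, numeric(1))
  d$score <- scores
  d <- d[!is.na(d$score), , drop = FALSE]
  subject_band_means(d, rep(TRUE, nrow(d)), col = "score")
}

#' Analyze an experiment-1-style dataset
#'
#' Runs the full first-experiment pipeline: normalize essay lengths within
#' subjects, restrict to analyzed words (`50 <= c <= 100`), compare
#' per-subject mean normalized lengths between the lower (`50 <= c <= 75`)
#' and upper (`75 < c <= 100`) confidence bands (Mann-Whitney, one-sided:
#' upper longer), and run the dot-product shuffle surrogate test. If an
#' embedding, tokenized essays and a word-components table are available, a
#' paired one-sided t-test additionally compares the semantic similarity of
#' essays to their word's components between bands (upper-band essays
#' hypothesized *less* similar, i.e. larger creative leap).
#'
#' @param data Behavioral data frame; may carry an `essay_tokens` list
#'   column and a `word_components` attribute (as produced by
#'   [generate_essays()]).
#' @param n_surrogate Surrogate draws for the shuffle test.
#' @param seed Optional integer seed (bootstrap + surrogates).
#' @param n_boot Bootstrap resamples for CIs.
#' @param embedding Optional [load_embedding()] /
#'   [generate_toy_embedding()] model.
#' @param word_components Optional data frame with `word_id`,
#'   `component_a`, `component_b`; defaults to the attribute on `data`.
#' @return Object of class `exp1_report`: `length_comparison`
#'   (a `group_comparison`), `dot_product_test` (a `surrogate_result`),
#'   `semantic_comparison` (a `group_comparison` or `NULL`), `n_subjects`.
#' @export
analyze_experiment1 <- function(data, n_surrogate = 1000L, seed = NULL,
                                n_boot = 2000L, embedding = NULL,
                                word_components = NULL) {
  if (!is.null(seed)) set.seed(seed)
  word_components <- word_components %||% attr(data, "word_components")
  norm <- normalize_lengths(data)
  analyzed <- norm[confidence_band(norm$confidence, "analyzed"), ,
                   drop = FALSE]
  if (!nrow(analyzed)) {
    stop("no words left in the analyzed confidence band", call. = FALSE)
  }
  lower <- subject_band_means(analyzed,
                              confidence_band(analyzed$confidence, "lower"))
  upper <- subject_band_means(analyzed,
                              confidence_band(analyzed$confidence, "upper"))
  if (length(lower) < 2L || length(upper) < 2L) {
    stop("too few subjects with words in both confidence bands",
         call. = FALSE)
  }
  length_cmp <- compare_groups(upper, lower, test = "mann-whitney",
                               alternative = "greater", n_boot = n_boot)
  dot <- dot_product_surrogate_test(norm, n_surrogate = n_surrogate)

  semantic_cmp <- NULL
  if (!is.null(embedding) && !is.null(word_components) &&
      "essay_tokens" %in% names(analyzed)) {
    sel <- analyzed[analyzed$essay_len > 0, , drop = FALSE]
    lo <- subject_semantic_means(
      sel[confidence_band(sel$confidence, "lower"), , drop = FALSE],
      embedding, word_components)
    hi <- subject_semantic_means(
      sel[confidence_band(sel$confidence, "upper"), , drop = FALSE],
      embedding, word_components)
    both <- intersect(names(lo), names(hi))
    if (length(both) >= 3L) {
      semantic_cmp <- compare_semantic_groups(hi[both], lo[both],
                                              mode = "paired",
                                              n_boot = n_boot)
    }
  }
  structure(list(length_comparison = length_cmp, dot_product_test = dot,
                 semantic_comparison = semantic_cmp,
                 n_subjects = length(unique(norm$subject_id))),
            class = "exp1_report")
}

#' Analyze an experiment-2-style dataset
#'
#' Runs the full second-experiment pipeline on a dataset containing both
#' spontaneous (once-presented) and forced (five-times-presented) words:
#'
#' * per-subject proportion (or count) of certain-rated (`c == 100`) words
#'   per condition, compared two-sided (forced presentation should inflate
#'   certainty);
#' * replication of the experiment-1 lower-vs-upper length comparison on
#'   once-presented words only;
#' * spontaneous vs forced per-subject mean normalized lengths among
#'   upper-band words, and among certain words (one-sided: spontaneous
#'   longer);
#' * the letter-reassignment surrogate test on certain words;
#' * optionally, an independent one-sided t-test of semantic similarity for
#'   upper-band selected words (spontaneous hypothesized less similar).
#'
#' @inheritParams analyze_experiment1
#' @param certain_as `"proportion"` (default) scales certain-word counts by
#'   the number of words in the condition; `"count"` uses raw counts.
#' @return Object of class `exp2_report` with components
#'   `certain_comparison`, `replication_comparison`, `upper_comparison`,
#'   `certain_length_comparison`, `letter_test`, `semantic_comparison`,
#'   `n_subjects`.
#' @export
analyze_experiment2 <- function(data, n_surrogate = 1000L, seed = NULL,
                                n_boot = 2000L, embedding = NULL,
                                word_components = NULL,
                                certain_as = c("proportion", "count")) {
  certain_as <- match.arg(certain_as)
  if (!is.null(seed)) set.seed(seed)
  word_components <- word_components %||% attr(data, "word_components")
  validate_behavior_data(data)
  if (!any(data$condition == "forced")) {
    stop("dataset has no forced-condition words", call. = FALSE)
  }
  norm <- normalize_lengths(data)

  per_cond <- function(cond) {
    d <- norm[norm$condition == cond, , drop = FALSE]
    cnt <- tapply(confidence_band(d$confidence, "certain"), d$subject_id,
                  sum)
    if (certain_as == "proportion") {
      tot <- tapply(d$confidence, d$subject_id, length)
      cnt <- cnt / tot
    }
    stats::setNames(as.numeric(cnt), names(cnt))
  }
  spont_cert <- per_cond("spontaneous")
  forc_cert <- per_cond("forced")
  certain_cmp <- compare_groups(forc_cert, spont_cert,
                                test = "mann-whitney",
                                alternative = "two.sided", n_boot = n_boot)

  once <- norm[norm$condition == "spontaneous" &
                 confidence_band(norm$confidence, "analyzed"), ,
               drop = FALSE]
  repl <- compare_groups(
    subject_band_means(once, confidence_band(once$confidence, "upper")),
    subject_band_means(once, confidence_band(once$confidence, "lower")),
    test = "mann-whitney", alternative = "greater", n_boot = n_boot)

  band_cond_cmp <- function(band) {
    in_band <- confidence_band(norm$confidence, band)
    compare_groups(
      subject_band_means(norm, in_band & norm$condition == "spontaneous"),
      subject_band_means(norm, in_band & norm$condition == "forced"),
      test = "mann-whitney", alternative = "greater", n_boot = n_boot)
  }
  upper_cmp <- band_cond_cmp("upper")
  certain_len_cmp <- band_cond_cmp("certain")

  letter <- letter_reassignment_surrogate_test(norm,
                                               n_surrogate = n_surrogate)

  semantic_cmp <- NULL
  if (!is.null(embedding) && !is.null(word_components) &&
      "essay_tokens" %in% names(norm)) {
    sel <- norm[norm$essay_len > 0 &
                  confidence_band(norm$confidence, "upper"), , drop = FALSE]
    sp <- subject_semantic_means(
      sel[sel$condition == "spontaneous", , drop = FALSE],
      embedding, word_components)
    fo <- subject_semantic_means(
      sel[sel$condition == "forced", , drop = FALSE],
      embedding, word_components)
    if (length(sp) >= 3L && length(fo) >= 3L) {
      semantic_cmp <- compare_semantic_groups(sp, fo, mode = "independent",
                                              n_boot = n_boot)
    }
  }
  structure(list(certain_comparison = certain_cmp,
                 replication_comparison = repl,
                 upper_comparison = upper_cmp,
                 certain_length_comparison = certain_len_cmp,
                 letter_test = letter,
                 semantic_comparison = semantic_cmp,
                 n_subjects = length(unique(norm$subject_id))),
            class = "exp2_report")
}

#' @export
print.exp1_report <- function(x, ...) {
  cat(sprintf("<exp1_report> %d subjects\n", x$n_subjects))
  cat("-- upper vs lower confidence band, normalized essay length --\n")
  print(x$length_comparison)
  cat("-- confidence/length dot-product shuffle test --\n")
  print(x$dot_product_test)
  if (!is.null(x$semantic_comparison)) {
    cat("-- semantic similarity, upper vs lower band (paired) --\n")
    print(x$semantic_comparison)
  }
  invisible(x)
}

#' @export
print.exp2_report <- function(x, ...) {
  cat(sprintf("<exp2_report> %d subjects\n", x$n_subjects))
  cat("-- certain-rated words per condition (forced vs spontaneous) --\n")
  print(x$certain_comparison)
  cat("-- replication: upper vs lower band, once-presented words --\n")
  print(x$replication_comparison)
  cat("-- spontaneous vs forced, upper band --\n")
  print(x$upper_comparison)
  cat("-- spontaneous vs forced, certain words --\n")
  print(x$certain_length_comparison)
  cat("-- letter-reassignment surrogate test --\n")
  print(x$letter_test)
  if (!is.null(x$semantic_comparison)) {
    cat("-- semantic similarity, spontaneous vs forced (independent) --\n")
    print(x$semantic_comparison)
  }
  invisible(x)
}
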