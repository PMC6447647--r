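#' Configuration for the synthetic behavioral-data generator
#'
#' Describes a cohort for the word-acquisition / essay-production design:
#' each subject sees `n_words` novel compositional words, `n_forced` of
#' which (chosen at random per subject) are presented five times per block
#' (forced memorization) while the rest are presented once (spontaneous);
#' the subject then rates recognition confidence 0-100 per word and writes
#' essays for a self-selected subset of words.
#'
#' The generative model: each subject x word has a latent salience
#' `s ~ N(0, 1)`. Confidence is a clamped rounded Gaussian
#' `conf_center + conf_scale * (conf_effect * s + sqrt(1 - conf_effect^2) * noise)`,
#' plus `forced_conf_boost` for forced words (forced presentation inflates
#' certainty). Words are selected for essays with probability
#' `plogis(qlogis(selection_rate) + length_effect * s)`; the subject's
#' total letter budget is lognormal with mean `total_letters_mean`, and is
#' allocated over the selected words by a multinomial with weights
#' `exp(length_effect * s)`. With `length_effect = 0` and
#' `forced_conf_boost = 0` the dataset satisfies the null hypothesis of
#' every analysis in the package: selection and letter allocation are
#' uniform and independent of confidence and condition (letters are
#' exchangeable, and conditionally multinomial-uniform over any word
#' subset), while positive effects plant monotone confidence-length and
#' condition structure.
#'
#' @param n_subjects Number of subjects.
#' @param n_words Words per subject.
#' @param n_forced Forced (five-times-presented) words per subject; 0
#'   gives an experiment-1-style design.
#' @param conf_effect Weight in \[0, 1\] of salience in the confidence
#'   rating (0 = confidence pure noise).
#' @param forced_conf_boost Additive confidence inflation for forced words
#'   (rating points).
#' @param length_effect Strength (>= 0) of the salience -> essay
#'   selection/length association; 0 is the null model.
#' @param selection_rate Baseline probability that a word is selected for
#'   an essay.
#' @param semantic_leap Mixture weight in \[0, 1\] steering essay tokens
#'   away from the word's own component cluster (see [generate_essays()]).
#' @param total_letters_mean Mean total essay letters per subject.
#' @param letters_sdlog Lognormal sdlog of the letter budget.
#' @param conf_center,conf_scale Location/scale of the confidence rating
#'   before clamping to \[0, 100\]. The defaults put ~15% of
#'   once-presented words at the certainty ceiling (rating 100) and ~77%
#'   in the analyzed band, matching the certainty rates reported for this
#'   task design.
#' @param letters_per_token Characters per token when converting essay
#'   lengths to token counts.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 30L, n_words = 20L,
                             n_forced = 2L,
                             conf_effect = 0.5, forced_conf_boost = 35,
                             length_effect = 1.0, selection_rate = 0.5,
                             semantic_leap = 0.3,
                             total_letters_mean = 800,
                             letters_sdlog = 0.3,
                             conf_center = 70, conf_scale = 28,
                             letters_per_token = 10) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_words = as.integer(n_words),
              n_forced = as.integer(n_forced),
              conf_effect = conf_effect,
              forced_conf_boost = forced_conf_boost,
              length_effect = length_effect,
              selection_rate = selection_rate,
              semantic_leap = semantic_leap,
              total_letters_mean = total_letters_mean,
              letters_sdlog = letters_sdlog,
              conf_center = conf_center, conf_scale = conf_scale,
              letters_per_token = letters_per_token)
  stopifnot(cfg$n_subjects >= 1L, cfg$n_words >= 2L,
            cfg$n_forced >= 0L, cfg$n_forced < cfg$n_words,
            cfg$conf_effect >= 0, cfg$conf_effect <= 1,
            cfg$length_effect >= 0,
            cfg$selection_rate > 0, cfg$selection_rate <= 1,
            cfg$semantic_leap >= 0, cfg$semantic_leap <= 1,
            cfg$total_letters_mean > 0, cfg$letters_sdlog >= 0)
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic behavioral dataset
#'
#' Draws a full cohort under the model described in [generator_config()].
#' Deterministic given `seed`.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed.
#' @return A behavioral data frame (see [validate_behavior_data()]) with
#'   one row per subject x word and columns `subject_id`, `word_id`,
#'   `condition`, `confidence`, `essay_len`, plus a hidden `salience`
#'   column (the latent truth, for diagnostics).
#' @export
generate_dataset <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  word_ids <- sprintf("w%02d", seq_len(cfg$n_words))
  rows <- lapply(seq_len(cfg$n_subjects), function(si) {
    forced_idx <- if (cfg$n_forced > 0)
      sample.int(cfg$n_words, cfg$n_forced) else integer(0)
    condition <- rep("spontaneous", cfg$n_words)
    condition[forced_idx] <- "forced"
    sal <- stats::rnorm(cfg$n_words)
    eps <- stats::rnorm(cfg$n_words)
    raw_conf <- cfg$conf_center + cfg$conf_scale *
      (cfg$conf_effect * sal + sqrt(1 - cfg$conf_effect^2) * eps)
    raw_conf[forced_idx] <- raw_conf[forced_idx] + cfg$forced_conf_boost
    confidence <- pmin(100, pmax(0, round(raw_conf)))

    p_sel <- stats::plogis(stats::qlogis(cfg$selection_rate) +
                             cfg$length_effect * sal)
    selected <- stats::runif(cfg$n_words) < p_sel
    if (!any(selected)) selected[sample.int(cfg$n_words, 1L)] <- TRUE
    total <- max(20, round(stats::rlnorm(
      1, log(cfg$total_letters_mean) - cfg$letters_sdlog^2 / 2,
      cfg$letters_sdlog)))
    w <- exp(cfg$length_effect * sal[selected])
    essay_len <- numeric(cfg$n_words)
    essay_len[selected] <- drop(stats::rmultinom(1, total, w / sum(w)))
    data.frame(subject_id = sprintf("s%03d", si), word_id = word_ids,
               condition = condition, confidence = confidence,
               essay_len = essay_len, salience = sal)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specification of a toy clustered embedding
#'
#' Stand-in geometry for a corpus-trained embedding: `n_clusters` mutually
#' orthogonal centroids, each carrying `tokens_per_cluster` unit token
#' vectors whose pairwise within-cluster cosine targets
#' `within_cluster_cos`; between-cluster cosines are near 0. The first two
#' tokens of each cluster are designated component words
#' (`c<k>_a`, `c<k>_b`); the rest are essay tokens (`c<k>_t<j>`).
#'
#' @param n_clusters Number of clusters (<= `dim`).
#' @param tokens_per_cluster Tokens per cluster (>= 3).
#' @param dim Embedding dimension.
#' @param within_cluster_cos Target mean intra-cluster cosine, in (0, 1).
#' @return Object of class `toy_embedding_spec`.
#' @export
toy_embedding_spec <- function(n_clusters = 8L, tokens_per_cluster = 12L,
                               dim = 50L, within_cluster_cos = 0.7) {
  spec <- list(n_clusters = as.integer(n_clusters),
               tokens_per_cluster = as.integer(tokens_per_cluster),
               dim = as.integer(dim),
               within_cluster_cos = within_cluster_cos)
  if (spec$n_clusters > spec$dim) {
    stop("infeasible geometry: n_clusters must not exceed dim",
         call. = FALSE)
  }
  stopifnot(spec$tokens_per_cluster >= 3L,
            spec$within_cluster_cos > 0, spec$within_cluster_cos < 1)
  class(spec) <- "toy_embedding_spec"
  spec
}

#' Generate a toy clustered embedding
#'
#' Centroids are an exactly orthonormal random basis subset; each token is
#' `sqrt(rho) * centroid + sqrt(1 - rho) * u`, with `u` a unit vector drawn
#' orthogonal to the centroid, so that the expected cosine between two
#' tokens of one cluster is `rho = within_cluster_cos` and every token is
#' exactly unit length (self-similarity 1).
#'
#' @param spec A [toy_embedding_spec()].
#' @param seed Optional integer seed.
#' @return An `embedding_model` with attribute `clusters` (integer cluster
#'   id per token) and attribute `components` (data frame `cluster`,
#'   `component_a`, `component_b`).
#' @export
generate_toy_embedding <- function(spec = toy_embedding_spec(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- spec$dim
  K <- spec$n_clusters
  m <- spec$tokens_per_cluster
  basis <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))[, seq_len(K),
                                                       drop = FALSE]
  rho <- spec$within_cluster_cos
  tokens <- character(0)
  vecs <- matrix(0, K * m, d)
  clusters <- integer(K * m)
  row <- 0L
  for (k in seq_len(K)) {
    cen <- basis[, k]
    for (j in seq_len(m)) {
      g <- stats::rnorm(d)
      g <- g - sum(g * cen) * cen
      u <- g / sqrt(sum(g^2))
      v <- sqrt(rho) * cen + sqrt(1 - rho) * u
      row <- row + 1L
      vecs[row, ] <- v
      clusters[row] <- k
      tokens <- c(tokens, if (j == 1L) sprintf("c%d_a", k)
                  else if (j == 2L) sprintf("c%d_b", k)
                  else sprintf("c%d_t%d", k, j - 2L))
    }
  }
  rownames(vecs) <- tokens
  model <- new_embedding(vecs)
  attr(model, "clusters") <- clusters
  attr(model, "components") <- data.frame(
    cluster = seq_len(K),
    component_a = sprintf("c%d_a", seq_len(K)),
    component_b = sprintf("c%d_b", seq_len(K)))
  model
}

#' Attach synthetic essays to a behavioral dataset
#'
#' Gives every selected word (nonzero essay length) a pre-tokenized essay
#' drawn from the toy embedding: the word is assigned a component cluster
#' (round-robin over clusters by word index, shared across subjects, with
#' that cluster's two designated component words), and each of its
#' `ceiling(essay_len / letters_per_token)` tokens is drawn from the word's
#' own cluster's non-component tokens with probability
#' `1 - semantic_leap`, otherwise uniformly from the other clusters'
#' non-component tokens. The expected essay-to-component similarity thus
#' decreases strictly as `semantic_leap` grows from 0 (essays stay in the
#' components' semantic neighborhood) to 1 (essays leap away entirely).
#'
#' @param data A behavioral data frame from [generate_dataset()].
#' @param embedding A [generate_toy_embedding()] model (needs its
#'   `clusters`/`components` attributes).
#' @param cfg The [generator_config()] (uses `semantic_leap`,
#'   `letters_per_token`).
#' @param seed Optional integer seed.
#' @return The data with an added `essay_tokens` list column and a
#'   `word_components` attribute (`word_id`, `component_a`,
#'   `component_b`).
#' @export
generate_essays <- function(data, embedding, cfg = generator_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clusters <- attr(embedding, "clusters")
  comps <- attr(embedding, "components")
  if (is.null(clusters) || is.null(comps)) {
    stop("embedding lacks cluster annotations; use generate_toy_embedding()",
         call. = FALSE)
  }
  vocab <- embedding$vocabulary
  is_comp <- vocab %in% c(comps$component_a, comps$component_b)
  word_ids <- sort(unique(data$word_id))
  K <- nrow(comps)
  word_cluster <- stats::setNames(((seq_along(word_ids) - 1L) %% K) + 1L,
                                  word_ids)
  word_components <- data.frame(
    word_id = word_ids,
    component_a = comps$component_a[word_cluster],
    component_b = comps$component_b[word_cluster])

  own_pool <- lapply(seq_len(K), function(k)
    vocab[clusters == k & !is_comp])
  other_pool <- lapply(seq_len(K), function(k)
    vocab[clusters != k & !is_comp])

  data$essay_tokens <- vector("list", nrow(data))
  sel <- which(data$essay_len > 0)
  for (i in sel) {
    k <- word_cluster[[data$word_id[i]]]
    n_tok <- max(1L, ceiling(data$essay_len[i] / cfg$letters_per_token))
    leap <- stats::runif(n_tok) < cfg$semantic_leap
    toks <- character(n_tok)
    if (any(!leap)) toks[!leap] <- sample(own_pool[[k]], sum(!leap),
                                          replace = TRUE)
    if (any(leap)) toks[leap] <- sample(other_pool[[k]], sum(leap),
                                        replace = TRUE)
    data$essay_tokens[[i]] <- toks
  }
  attr(data, "word_components") <- word_components
  data
}
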