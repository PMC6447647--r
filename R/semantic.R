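#' Load a word-embedding model from word2vec text format
#'
#' Reads the plain-text word2vec format: a header line
#' `"<vocab_size> <dim>"` followed by one line per token, the token then
#' `dim` floats, space-separated. Duplicate tokens are resolved last-wins
#' with a warning; a malformed line or a dimension mismatch is a parse
#' error reporting the line number.
#'
#' @param path Path to the embedding file.
#' @return Object of class `embedding_model`: `vectors` (matrix, one row
#'   per token, rownames = tokens), `dim`, `vocabulary`.
#' @export
load_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty embedding file", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("line 1: malformed word2vec header (expected '<count> <dim>')",
         call. = FALSE)
  }
  n <- as.integer(header[1])
  dim <- as.integer(header[2])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != n) {
    stop(sprintf("header declares %d tokens but file has %d vector lines",
                 n, length(body)), call. = FALSE)
  }
  tokens <- character(n)
  vecs <- matrix(NA_real_, n, dim)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != dim + 1L) {
      stop(sprintf("line %d: expected token + %d values, found %d fields",
                   i + 1L, dim, length(parts)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric vector component", i + 1L),
           call. = FALSE)
    }
    tokens[i] <- parts[1]
    vecs[i, ] <- vals
  }
  if (anyDuplicated(tokens)) {
    warning("duplicate tokens in embedding file; keeping the last occurrence")
    keep <- !duplicated(tokens, fromLast = TRUE)
    tokens <- tokens[keep]
    vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- tokens
  new_embedding(vecs)
}

new_embedding <- function(vecs) {
  structure(list(vectors = vecs, dim = ncol(vecs),
                 vocabulary = rownames(vecs)),
            class = "embedding_model")
}

#' Write an embedding model in word2vec text format
#'
#' Inverse of [load_embedding()]; useful for persisting toy embeddings.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dim), con)
  apply_fmt <- apply(model$vectors, 1L, function(v)
    paste(formatC(v, format = "g", digits = 8), collapse = " "))
  writeLines(paste(rownames(model$vectors), apply_fmt), con)
  invisible(path)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d tokens, dimension %d\n",
              length(x$vocabulary), x$dim))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `dot(u, v) / (|u| |v|)` in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity of a zero vector",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

embedding_vector <- function(model, token) {
  i <- match(token, rownames(model$vectors))
  if (is.na(i)) NULL else model$vectors[i, ]
}

#' Similarity of a token to the closer of two component words
#'
#' For one essay token and a compositional word made of two components,
#' computes the cosine similarity to each component and returns the larger
#' of the two (the token is judged by the component it is closer to).
#'
#' @param model An `embedding_model`.
#' @param token A token present in the vocabulary.
#' @param component_a,component_b The two component words (in vocabulary).
#' @return Similarity in \[-1, 1\].
#' @export
token_component_similarity <- function(model, token, component_a,
                                       component_b) {
  tv <- embedding_vector(model, token)
  av <- embedding_vector(model, component_a)
  bv <- embedding_vector(model, component_b)
  if (is.null(tv) || is.null(av) || is.null(bv)) {
    stop("token or component out of vocabulary", call. = FALSE)
  }
  max(cosine_similarity(tv, av), cosine_similarity(tv, bv))
}

#' Mean semantic similarity between an essay and a word's components
#'
#' Scores an essay against the two components of its compositional word:
#' each token contributes its larger cosine similarity to the two
#' components ([token_component_similarity()]); tokens identical to either
#' component are excluded, out-of-vocabulary tokens are skipped and
#' counted, duplicate tokens count once per occurrence. The score is the
#' mean contribution. With no usable token the score is undefined
#' (`defined = FALSE`), not zero.
#'
#' Low similarity is read as a large "creative leap" away from the
#' components.
#'
#' @param model An `embedding_model`.
#' @param tokens Character vector of essay tokens (nonempty).
#' @param component_a,component_b Component words.
#' @return List with `mean_similarity`, `n_tokens_used`, `n_oov`,
#'   `n_component_excluded`, `defined`.
#' @export
essay_similarity <- function(model, tokens, component_a, component_b) {
  if (!length(tokens)) stop("essay has no tokens", call. = FALSE)
  is_comp <- tokens %in% c(component_a, component_b)
  tokens2 <- tokens[!is_comp]
  in_vocab <- tokens2 %in% rownames(model$vectors)
  usable <- tokens2[in_vocab]
  if (!length(usable)) {
    return(list(mean_similarity = NA_real_, n_tokens_used = 0L,
                n_oov = sum(!in_vocab),
                n_component_excluded = sum(is_comp), defined = FALSE))
  }
  av <- embedding_vector(model, component_a)
  bv <- embedding_vector(model, component_b)
  if (is.null(av) || is.null(bv)) {
    stop("component word out of vocabulary", call. = FALSE)
  }
  vecs <- model$vectors[usable, , drop = FALSE]
  norms <- sqrt(rowSums(vecs^2))
  sa <- drop(vecs %*% av) / (norms * sqrt(sum(av^2)))
  sb <- drop(vecs %*% bv) / (norms * sqrt(sum(bv^2)))
  sims <- pmax(sa, sb)
  list(mean_similarity = mean(sims), n_tokens_used = length(usable),
       n_oov = sum(!in_vocab), n_component_excluded = sum(is_comp),
       defined = TRUE)
}

#' Compare semantic similarity scores between two groups
#'
#' One-sided t-test of per-subject mean essay-to-component similarities in
#' the direction "group `a` is *less* similar than group `b`" (a larger
#' creative leap for the hypothesized group), with d_z (paired) or Cohen's
#' d (independent) as effect size, via [compare_groups()].
#'
#' @param scores_a,scores_b Numeric score vectors (paired mode: same
#'   length, same subject order).
#' @param mode `"paired"` or `"independent"`.
#' @param alternative Direction for `a` relative to `b`; default `"less"`.
#' @param n_boot Bootstrap resamples for CIs.
#' @param seed Optional seed.
#' @return A `group_comparison`.
#' @export
compare_semantic_groups <- function(scores_a, scores_b,
                                    mode = c("paired", "independent"),
                                    alternative = "less",
                                    n_boot = 2000L, seed = NULL) {
  mode <- match.arg(mode)
  compare_groups(scores_a, scores_b,
                 test = if (mode == "paired") "paired-t" else "t",
                 alternative = alternative, n_boot = n_boot, seed = seed)
}
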