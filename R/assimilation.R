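#' Mean within-assembly weight over a time window
#'
#' Averages the six directed member-to-member weights of a cell assembly
#' over all recorded samples falling in the closed window `[t0, t1]`. The
#' recording must have been made with the assembly's edges in
#' `record_edges`.
#'
#' @param rec A `net_recording` with recorded edge weights.
#' @param members Integer vector of 3 member indices.
#' @param window Numeric length-2, window in ms (closed).
#' @return Mean weight (scalar).
#' @export
window_mean_weight <- function(rec, members, window) {
  if (is.null(rec$w)) stop("recording has no edge-weight trace", call. = FALSE)
  sel <- rec$times >= window[1] & rec$times <= window[2]
  if (!any(sel)) stop("window contains no recorded samples", call. = FALSE)
  ed <- assembly_edges(members)
  key <- paste(rec$record_edges[, 1L], rec$record_edges[, 2L])
  pos <- match(paste(ed[, 1L], ed[, 2L]), key)
  if (anyNA(pos)) {
    stop("assembly edges were not recorded; pass them in record_edges",
         call. = FALSE)
  }
  mean(rec$w[sel, pos])
}

#' Within- and out-of-assembly activity correlations over a time window
#'
#' Pearson correlations of the excitatory voltage traces restricted to the
#' closed window `[t0, t1]`: the within value averages the three member
#' pairs; the out value averages all member x non-member pairs. Pairs
#' involving a zero-variance trace are excluded from the means (their count
#' is returned).
#'
#' @param rec A `net_recording`.
#' @param members Integer vector of 3 member indices.
#' @param window Numeric length-2, ms.
#' @param cor_matrix Optional precomputed correlation matrix of all
#'   excitatory traces over the same window (as from
#'   [window_cor_matrix()]); avoids recomputation across many assemblies.
#' @param on Correlate `"voltage"` (default) or `"rate"` traces; ignored
#'   when `cor_matrix` is supplied.
#' @return List with `within`, `out`, `n_dropped`.
#' @export
window_correlations <- function(rec, members, window, cor_matrix = NULL,
                                on = "voltage") {
  if (is.null(cor_matrix)) cor_matrix <- window_cor_matrix(rec, window, on)
  n_ex <- ncol(cor_matrix)
  members <- as.integer(members)
  pairs <- utils::combn(members, 2L)
  within_vals <- cor_matrix[t(pairs)]
  outside <- setdiff(seq_len(n_ex), members)
  out_vals <- cor_matrix[members, outside]
  list(within = mean(within_vals, na.rm = TRUE),
       out = mean(out_vals, na.rm = TRUE),
       n_dropped = sum(is.na(within_vals)) + sum(is.na(out_vals)))
}

#' Correlation matrix of excitatory voltage traces over a window
#'
#' @param rec A `net_recording`.
#' @param window Numeric length-2, ms (closed window).
#' @param on `"voltage"` correlates the raw membrane voltages (default);
#'   `"rate"` correlates the threshold-linear firing rates `F(v)`.
#' @return `n_ex` x `n_ex` Pearson correlation matrix; entries involving a
#'   zero-variance trace are `NA`.
#' @export
window_cor_matrix <- function(rec, window, on = c("voltage", "rate")) {
  on <- match.arg(on)
  sel <- rec$times >= window[1] & rec$times <= window[2]
  if (sum(sel) < 3L) stop("need at least 3 samples in the window",
                          call. = FALSE)
  v <- rec$v_ex[sel, , drop = FALSE]
  if (on == "rate") v <- activation(v, rec$params$theta_act)
  sds <- apply(v, 2L, stats::sd)
  suppressWarnings(cm <- stats::cor(v))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  cm
}

#' Cell-assembly assimilation experiment
#'
#' For each of `n_topologies` independently drawn network topologies: run
#' the network to `t_insert` ms (burn-in to a stationary state), insert
#' `n_assemblies` randomly selected three-neuron cell assemblies (all at
#' `t_insert`, new member-to-member edges created with weight zero), and
#' continue to `t_end` ms. For every assembly the assimilation strength is
#' the mean of its six internal weights over `weight_window`, and the
#' accessibility measures are the mean within-member and member-to-rest
#' voltage correlations over `corr_window` (which precedes the insertion,
#' so they characterize the pre-existing dynamics at the assembly's
#' location). Per topology, Pearson correlations (and p-values) across
#' assemblies are computed between assimilation strength and each
#' correlation measure.
#'
#' @param params A [sim_params()] object.
#' @param n_assemblies Number of assemblies per topology (>= 3).
#' @param n_topologies Number of independent topologies.
#' @param policy Assembly selection policy, see [select_assemblies()].
#' @param t_insert Insertion time (ms).
#' @param t_end End time (ms).
#' @param corr_window,weight_window Measurement windows (ms).
#' @param record_every Sampling cadence in steps.
#' @param insertion `"joint"` (default): all assemblies share one run per
#'   topology; `"sequential"`: one run per assembly (slower; identical
#'   predictor variables since correlations are measured pre-insertion).
#' @param correlate_on Activity variable for the correlation measures:
#'   `"voltage"` (default) or `"rate"`.
#' @param seed Optional integer seed.
#' @param engine Simulation engine, see [run_simulation()].
#' @param verbose Print per-topology progress.
#' @return Object of class `assimilation_experiment`: `summary` (data frame
#'   with one row per topology: `trial`, `r_within`, `p_within`,
#'   `r_between`, `p_between`, `failed`), and `assemblies` (per-assembly
#'   data frame with members, `mean_within_weight`, `mean_within_corr`,
#'   `mean_out_corr`).
#' @export
run_assimilation_experiment <- function(params = sim_params(),
                                        n_assemblies = 100L,
                                        n_topologies = 10L,
                                        policy = "random",
                                        t_insert = 50000,
                                        t_end = 90000,
                                        corr_window = c(30000, 50000),
                                        weight_window = c(70000, 90000),
                                        record_every = 10L,
                                        insertion = c("joint", "sequential"),
                                        correlate_on = "voltage",
                                        seed = NULL,
                                        engine = "cpp",
                                        verbose = FALSE) {
  insertion <- match.arg(insertion)
  if (n_assemblies < 3L) {
    stop("need at least 3 assemblies for a correlation across assemblies",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  summaries <- vector("list", n_topologies)
  all_assemblies <- vector("list", n_topologies)

  for (trial in seq_len(n_topologies)) {
    topo <- build_topology(params)
    assemblies <- select_assemblies(n_assemblies, params$n_ex, policy)
    res <- tryCatch(
      assimilation_trial(params, topo, assemblies, t_insert, t_end,
                         corr_window, weight_window, record_every,
                         insertion, engine, correlate_on),
      assimnet_divergence = function(e) NULL)
    if (is.null(res)) {
      summaries[[trial]] <- data.frame(trial = trial, r_within = NA_real_,
                                       p_within = NA_real_,
                                       r_between = NA_real_,
                                       p_between = NA_real_, failed = TRUE)
      next
    }
    res$trial <- trial
    all_assemblies[[trial]] <- res
    ct_w <- stats::cor.test(res$mean_within_weight, res$mean_within_corr)
    ct_b <- stats::cor.test(res$mean_within_weight, res$mean_out_corr)
    summaries[[trial]] <- data.frame(
      trial = trial,
      r_within = unname(ct_w$estimate), p_within = ct_w$p.value,
      r_between = unname(ct_b$estimate), p_between = ct_b$p.value,
      failed = FALSE)
    if (verbose) {
      message(sprintf("topology %d/%d: r_within = %.3f, r_between = %.3f",
                      trial, n_topologies, unname(ct_w$estimate),
                      unname(ct_b$estimate)))
    }
  }
  structure(list(summary = do.call(rbind, summaries),
                 assemblies = do.call(rbind, all_assemblies),
                 params = params),
            class = "assimilation_experiment")
}

assimilation_trial <- function(params, topo, assemblies, t_insert, t_end,
                               corr_window, weight_window, record_every,
                               insertion, engine, correlate_on = "voltage") {
  measure <- function(rec, asm_list) {
    cm <- window_cor_matrix(rec, corr_window, on = correlate_on)
    do.call(rbind, lapply(seq_along(asm_list), function(a) {
      m <- asm_list[[a]]
      wc <- window_correlations(rec, m, corr_window, cor_matrix = cm)
      data.frame(assembly = a, m1 = m[1], m2 = m[2], m3 = m[3],
                 mean_within_weight = window_mean_weight(rec, m,
                                                         weight_window),
                 mean_within_corr = wc$within,
                 mean_out_corr = wc$out)
    }))
  }
  if (insertion == "joint") {
    events <- lapply(assemblies, function(m) list(time = t_insert,
                                                  members = m))
    edges <- unique(do.call(rbind, lapply(assemblies, assembly_edges)))
    rec <- run_simulation(params, topo, t_end, events = events,
                          record_every = record_every,
                          record_edges = edges, engine = engine)
    out <- measure(rec, assemblies)
  } else {
    out <- do.call(rbind, lapply(seq_along(assemblies), function(a) {
      m <- assemblies[[a]]
      rec <- run_simulation(params, topo, t_end,
                            events = list(list(time = t_insert,
                                               members = m)),
                            record_every = record_every,
                            record_edges = assembly_edges(m),
                            engine = engine)
      df <- measure(rec, list(m))
      df$assembly <- a
      df
    }))
  }
  out
}

#' @export
print.assimilation_experiment <- function(x, ...) {
  cat(sprintf("<assimilation_experiment> %d topolog%s, %d assemblies each\n",
              nrow(x$summary), if (nrow(x$summary) == 1) "y" else "ies",
              if (is.null(x$assemblies)) 0L
              else max(x$assemblies$assembly)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
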