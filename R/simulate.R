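#' Run the plastic network simulation
#'
#' Integrates the full model from `t = 0` to `t_end`: at every `dt` step the
#' voltages advance by one RK4 step (noise frozen across stages), the
#' sliding BCM thresholds advance by one EMA step, every plastic
#' excitatory-to-excitatory weight advances by one Euler step of the BCM
#' rule (clamped at zero from below), and synaptic scaling renormalizes each
#' neuron's incoming plastic weights to `kappa`. Scheduled structural events
#' insert three-neuron cell assemblies: at the event time all missing
#' directed edges among the members are created with weight zero and start
#' participating in the dynamics, preserving reciprocity.
#'
#' Excitatory voltages (and optionally a designated set of edge weights) are
#' sampled every `record_every` steps, including the initial state.
#'
#' @param params A [sim_params()] object.
#' @param topo A [build_topology()] topology.
#' @param t_end End time (ms); must be a multiple of `dt`.
#' @param events Optional list of assembly insertions, each a list with
#'   `time` (ms, multiple of `dt`, within `[0, t_end]`) and `members`
#'   (3 distinct excitatory indices).
#' @param record_every Sampling cadence in steps (default 10, i.e. every
#'   5 ms at the default `dt`).
#' @param record_edges Optional integer matrix (columns `post`, `pre`) of
#'   directed excitatory edges whose weights are recorded. Edges may be
#'   base-topology edges or event-inserted ones.
#' @param engine `"cpp"` (compiled, default) or `"r"` (step-by-step
#'   reference implementation; identical semantics, for small problems).
#' @param seed Optional integer; if given, `set.seed(seed)` is called
#'   first. Identical seeds and inputs give identical recordings.
#' @param init Optional list overriding initial conditions: `v_ex`,
#'   `v_inh`, `theta_hat` (defaults 0, 0, `theta_act`).
#'
#' @return An object of class `net_recording`: `times` (sampled times, ms),
#'   `v_ex` (samples x `n_ex` voltage matrix), `w` (samples x edges weight
#'   matrix or `NULL`), `record_edges`, `events` (with the edges actually
#'   added), `params`, `n_degenerate` (skipped scaling operations),
#'   `max_scaling_dev` (largest deviation of a scaled incoming sum from
#'   `kappa` across the whole run), and `final_state`.
#'
#'   If the voltages diverge, an error of class `assimnet_divergence` is
#'   signalled whose condition carries the recording collected so far in
#'   `$recording` plus the failure `$time` and `$neuron`.
#' @export
run_simulation <- function(params, topo, t_end,
                           events = NULL, record_every = 10L,
                           record_edges = NULL,
                           engine = c("cpp", "r"), seed = NULL,
                           init = NULL) {
  engine <- match.arg(engine)
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n_steps <- as.integer(round(t_end / dt))
  if (abs(n_steps * dt - t_end) > 1e-9) {
    stop("t_end must be a multiple of dt", call. = FALSE)
  }
  events <- check_events(events, n_steps, dt, topo$n_ex)
  record_every <- as.integer(record_every)
  stopifnot(record_every >= 1L)

  # union edge set: base edges active from step 0, event edges from their step
  edges <- data.frame(post = as.integer(topo$ee[, "post"]),
                      pre = as.integer(topo$ee[, "pre"]),
                      active = rep(0L, nrow(topo$ee)))
  t2 <- topo
  for (k in seq_along(events)) {
    ins <- insert_assembly(t2, events[[k]]$members)
    t2 <- ins$topology
    events[[k]]$added_edges <- ins$added_edges
    if (nrow(ins$added_edges)) {
      edges <- rbind(edges, data.frame(post = ins$added_edges[, "post"],
                                       pre = ins$added_edges[, "pre"],
                                       active = events[[k]]$step))
    }
  }
  ord <- order(edges$post, edges$pre)
  edges <- edges[ord, , drop = FALSE]

  indeg0 <- tabulate(edges$post[edges$active == 0L], topo$n_ex)
  w0 <- ifelse(edges$active == 0L, params$kappa / indeg0[edges$post], 0)

  rec_pos <- integer(0)
  if (!is.null(record_edges)) {
    record_edges <- as.matrix(record_edges)
    key <- paste(edges$post, edges$pre)
    rec_pos <- match(paste(record_edges[, 1L], record_edges[, 2L]), key)
    if (anyNA(rec_pos)) {
      stop("record_edges contains edges absent from the topology and events",
           call. = FALSE)
    }
  }

  init <- init %||% list()
  v_ex0 <- rep_len(init$v_ex %||% 0, topo$n_ex)
  v_inh0 <- rep_len(init$v_inh %||% 0, topo$n_inh)
  theta0 <- rep_len(init$theta_hat %||% params$theta_act, topo$n_ex)

  if (engine == "cpp") {
    run_engine_cpp(params, topo, edges, w0, rec_pos, record_edges,
                   n_steps, record_every, v_ex0, v_inh0, theta0, events)
  } else {
    run_engine_r(params, topo, edges, w0, rec_pos, record_edges,
                 n_steps, record_every, v_ex0, v_inh0, theta0, events)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_events <- function(events, n_steps, dt, n_ex) {
  if (is.null(events)) return(list())
  lapply(events, function(e) {
    stopifnot(!is.null(e$time), !is.null(e$members))
    step <- as.integer(round(e$time / dt))
    if (abs(step * dt - e$time) > 1e-9 || step < 0L || step > n_steps) {
      stop("event times must be multiples of dt within [0, t_end]",
           call. = FALSE)
    }
    members <- as.integer(e$members)
    if (length(members) != 3L || anyDuplicated(members) ||
        any(members < 1L | members > n_ex)) {
      stop("event members must be 3 distinct excitatory indices",
           call. = FALSE)
    }
    list(time = e$time, step = step, members = members)
  })
}

run_engine_cpp <- function(params, topo, edges, w0, rec_pos, record_edges,
                           n_steps, record_every, v_ex0, v_inh0, theta0,
                           events) {
  row_ptr <- function(post, n) c(0L, cumsum(tabulate(post, n)))
  ei <- topo$ei[order(topo$ei[, "post"], topo$ei[, "pre"]), , drop = FALSE]
  ie <- topo$ie[order(topo$ie[, "post"], topo$ie[, "pre"]), , drop = FALSE]
  pars <- unclass(params)
  pars$sigma_centered <- as.integer(params$sigma_convention == "centered")
  out <- sim_core(
    topo$n_ex, topo$n_inh,
    row_ptr(edges$post, topo$n_ex), as.integer(edges$pre - 1L),
    as.numeric(w0), as.integer(edges$active),
    row_ptr(ei[, "post"], topo$n_ex), as.integer(ei[, "pre"] - 1L),
    row_ptr(ie[, "post"], topo$n_inh), as.integer(ie[, "pre"] - 1L),
    pars, n_steps, record_every,
    as.integer(rec_pos - 1L), v_ex0, v_inh0, theta0)

  ns <- out$n_samples
  rec <- new_recording(
    times = out$sample_steps[seq_len(ns)] * params$dt,
    v_ex = out$v_trace[seq_len(ns), , drop = FALSE],
    w = if (length(rec_pos)) out$w_trace[seq_len(ns), , drop = FALSE],
    record_edges = record_edges, events = events, params = params,
    n_degenerate = out$n_degenerate,
    max_scaling_dev = out$max_scaling_dev,
    final_state = list(v_ex = out$v_ex_final, v_inh = out$v_inh_final,
                       theta_hat = out$theta_hat_final,
                       w = data.frame(post = edges$post, pre = edges$pre,
                                      weight = out$w_final)))
  if (isTRUE(out$diverged)) {
    stop(errorCondition(
      sprintf("numerical divergence at t = %g ms (neuron %d)",
              out$div_step * params$dt, out$div_neuron),
      class = c("assimnet_divergence", "error", "condition"),
      recording = rec, time = out$div_step * params$dt,
      neuron = out$div_neuron))
  }
  rec
}

run_engine_r <- function(params, topo, edges, w0, rec_pos, record_edges,
                         n_steps, record_every, v_ex0, v_inh0, theta0,
                         events) {
  base_topo <- topo
  base_topo$ee <- as.matrix(edges[edges$active == 0L, c("post", "pre")])
  colnames(base_topo$ee) <- c("post", "pre")
  state <- net_state(params, base_topo, v_ex = v_ex0, v_inh = v_inh0,
                     theta_hat = theta0)
  pending <- edges[edges$active > 0L, , drop = FALSE]

  n_samp <- n_steps %/% record_every + 1L
  v_trace <- matrix(NA_real_, n_samp, topo$n_ex)
  w_trace <- if (length(rec_pos)) matrix(NA_real_, n_samp, length(rec_pos))
  steps_rec <- integer(n_samp)
  n_degenerate <- 0
  max_dev <- 0

  grab_w <- function() {
    if (!length(rec_pos)) return(NULL)
    state$W[cbind(edges$post[rec_pos], edges$pre[rec_pos])]
  }
  v_trace[1L, ] <- state$v_ex
  if (length(rec_pos)) w_trace[1L, ] <- grab_w()
  row <- 1L
  partial <- function(ns) {
    new_recording(times = steps_rec[seq_len(ns)] * params$dt,
                  v_ex = v_trace[seq_len(ns), , drop = FALSE],
                  w = if (length(rec_pos)) w_trace[seq_len(ns), , drop = FALSE],
                  record_edges = record_edges, events = events,
                  params = params, n_degenerate = n_degenerate,
                  max_scaling_dev = max_dev,
                  final_state = list(v_ex = state$v_ex, v_inh = state$v_inh,
                                     theta_hat = state$theta_hat,
                                     w = data.frame(post = edges$post,
                                                    pre = edges$pre,
                                                    weight = state$W[cbind(edges$post, edges$pre)])))
  }

  redraw <- params$noise_redraw_every %||% 1
  noise <- NULL
  for (s in seq_len(n_steps) - 1L) {
    if (nrow(pending) && any(pending$active == s)) {
      now <- pending[pending$active == s, , drop = FALSE]
      state$A[cbind(now$post, now$pre)] <- 1
      pending <- pending[pending$active != s, , drop = FALSE]
    }
    if (is.null(noise) || (is.finite(redraw) && s %% redraw == 0)) {
      noise <- draw_noise(params)
    }
    state <- tryCatch(step_voltages(state, params, noise),
                      assimnet_divergence = function(e) {
                        e$recording <- partial(row)
                        stop(e)
                      })
    state <- step_weights(state, params)
    scal_every <- params$scaling_every %||% 1L
    if (scal_every > 0L && (s + 1L) %% scal_every == 0L) {
      state <- withCallingHandlers(
        apply_synaptic_scaling(state, params),
        warning = function(w) invokeRestart("muffleWarning"))
      n_degenerate <- n_degenerate + attr(state, "n_degenerate")
      sums <- rowSums(state$W)[rowSums(state$A) > 0 & rowSums(state$W) > 0]
      if (length(sums)) max_dev <- max(max_dev, abs(sums - params$kappa))
    }
    if ((s + 1L) %% record_every == 0L) {
      row <- row + 1L
      steps_rec[row] <- s + 1L
      v_trace[row, ] <- state$v_ex
      if (length(rec_pos)) w_trace[row, ] <- grab_w()
    }
  }
  partial(row)
}

new_recording <- function(times, v_ex, w, record_edges, events, params,
                          n_degenerate, max_scaling_dev, final_state) {
  structure(list(times = times, v_ex = v_ex, w = w,
                 record_edges = record_edges, events = events,
                 params = params, n_degenerate = n_degenerate,
                 max_scaling_dev = max_scaling_dev,
                 final_state = final_state),
            class = "net_recording")
}

#' @export
print.net_recording <- function(x, ...) {
  cat(sprintf("<net_recording> %d samples over [%g, %g] ms, %d neurons\n",
              length(x$times), min(x$times), max(x$times), ncol(x$v_ex)))
  if (!is.null(x$w)) {
    cat(sprintf("  %d recorded edge weights\n", ncol(x$w)))
  }
  if (length(x$events)) {
    cat(sprintf("  %d assembly insertion(s) at t = %s ms\n", length(x$events),
                paste(unique(vapply(x$events, `[[`, 0, "time")),
                      collapse = ", ")))
  }
  cat(sprintf("  max scaling deviation %.2e, degenerate scaling ops: %g\n",
              x$max_scaling_dev, x$n_degenerate))
  invisible(x)
}

#' Fraction of supra-threshold samples per time window
#'
#' Utility for inspecting baseline activity: splits the recording into
#' consecutive windows of `window_ms` and returns, per window, the fraction
#' of (sample, neuron) pairs whose excitatory voltage is at or above the
#' activation threshold.
#'
#' @param rec A `net_recording`.
#' @param window_ms Window width in ms.
#' @return Data frame with `t_start`, `t_end`, `active_fraction`.
#' @export
activity_fraction <- function(rec, window_ms = 10000) {
  bins <- floor(rec$times / window_ms)
  above <- rowMeans(rec$v_ex >= rec$params$theta_act)
  agg <- tapply(above, bins, mean)
  data.frame(t_start = as.numeric(names(agg)) * window_ms,
             t_end = (as.numeric(names(agg)) + 1) * window_ms,
             active_fraction = as.numeric(agg))
}
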