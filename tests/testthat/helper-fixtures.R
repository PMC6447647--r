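# Small configurations and hand-built objects shared across tests

tiny_params <- function(...) {
  sim_params(n_ex = 30L, n_inh = 8L, ...)
}

# single isolated neuron driven by a constant current (no edges, no noise)
isolated_params <- function(current, dt = 0.5, tau = 20) {
  sim_params(n_ex = 1L, n_inh = 1L, p_ee = 0, p_ei = 0, p_ie = 0,
             tau_ex = tau, tau_inh = tau, dt = dt,
             noise_ex_mean = current, noise_ex_sd = 0,
             noise_inh_mean = 0, noise_inh_sd = 0)
}

# recording object with prescribed traces, for the window statistics
fake_recording <- function(times, v_ex = NULL, w = NULL,
                           record_edges = NULL,
                           params = sim_params(n_ex = max(3L, ncol(v_ex) %||% 3L))) {
  structure(list(times = times, v_ex = v_ex, w = w,
                 record_edges = record_edges, events = list(),
                 params = params, n_degenerate = 0, max_scaling_dev = 0,
                 final_state = NULL),
            class = "net_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# behavioral data frame from parallel vectors (one subject per list element)
make_behavior <- function(confidence, essay_len, condition = NULL) {
  do.call(rbind, lapply(seq_along(confidence), function(i) {
    n <- length(confidence[[i]])
    data.frame(
      subject_id = sprintf("s%02d", i),
      word_id = sprintf("w%02d", seq_len(n)),
      condition = condition[[i]] %||% rep("spontaneous", n),
      confidence = confidence[[i]],
      essay_len = essay_len[[i]])
  }))
}

# exhaustive pair-enumeration oracle for the probability of superiority
ps_oracle <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# three-token toy model realizing per-token component maxima 0.9 and 0.6
hand_embedding <- function() {
  v <- rbind(
    compA = c(1, 0, 0),
    compB = c(0, 1, 0),
    tok1  = c(0.9, sqrt(0.19), 0),
    tok2  = c(0.6, -0.8, 0))
  assimnet:::new_embedding(v)
}
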