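#' Initialize the network state
#'
#' Builds the evolving state of the network for a given topology: voltages
#' (default 0), the sliding-threshold estimates (default `theta_act`), and
#' the plastic excitatory weight matrix. Plastic weights start at
#' `kappa / indegree` on every existing excitatory edge so that each
#' neuron's incoming sum already equals the scaling target `kappa`.
#'
#' This dense-state representation backs the step-by-step reference engine
#' ([step_voltages()], [step_weights()], [apply_synaptic_scaling()]); long
#' production runs should use [run_simulation()] with the compiled engine.
#'
#' @param params A [sim_params()] object.
#' @param topo A [build_topology()] object.
#' @param v_ex,v_inh,theta_hat Optional initial values (recycled to
#'   population size).
#' @return An object of class `net_state`: voltages `v_ex`, `v_inh`,
#'   estimates `theta_hat`, time `t` (ms), update counter `n_updates`,
#'   dense weight matrix `W` (rows postsynaptic, nonzero only on edges),
#'   0/1 adjacency `A`, and fixed-connectivity matrices `EI`, `IE`.
#' @export
net_state <- function(params, topo, v_ex = 0, v_inh = 0,
                      theta_hat = params$theta_act) {
  n_ex <- topo$n_ex
  n_inh <- topo$n_inh
  A <- matrix(0, n_ex, n_ex)
  A[topo$ee] <- 1
  W <- matrix(0, n_ex, n_ex)
  indeg <- rowSums(A)
  has <- indeg > 0
  W[has, ] <- A[has, , drop = FALSE] * (params$kappa / indeg[has])
  EI <- matrix(0, n_ex, n_inh)
  EI[topo$ei] <- 1
  IE <- matrix(0, n_inh, n_ex)
  IE[topo$ie] <- 1
  structure(list(
    v_ex = rep_len(v_ex, n_ex), v_inh = rep_len(v_inh, n_inh),
    theta_hat = rep_len(theta_hat, n_ex), t = 0, n_updates = 0L,
    W = W, A = A, EI = EI, IE = IE
  ), class = "net_state")
}

#' @export
print.net_state <- function(x, ...) {
  cat(sprintf("<net_state> t = %g ms, %d E + %d I neurons, %d plastic edges\n",
              x$t, length(x$v_ex), length(x$v_inh), sum(x$A > 0)))
  invisible(x)
}

# voltage derivatives of both populations at a given state
rate_derivs <- function(v_ex, v_inh, state, params, I_ex, I_inh) {
  F_ex <- activation(v_ex, params$theta_act)
  F_inh <- activation(v_inh, params$theta_act)
  dve <- (-v_ex + drop(state$W %*% F_ex) +
            params$w_ei_fixed * drop(state$EI %*% F_inh) + I_ex) / params$tau_ex
  dvi <- (-v_inh + params$w_ie_fixed * drop(state$IE %*% F_ex) + I_inh) /
    params$tau_inh
  list(dve = dve, dvi = dvi)
}

#' Advance the voltages by one RK4 step
#'
#' One fourth-order Runge-Kutta step of the coupled voltage ODEs: each
#' excitatory neuron integrates a leak, recurrent excitatory drive through
#' the plastic weights, fixed inhibitory drive and its noise current; each
#' inhibitory neuron integrates a leak, fixed excitatory drive and its noise
#' current. The noise currents are held constant across the four RK4 stages.
#' Weights and thresholds are not touched.
#'
#' @param state A [net_state()].
#' @param params A [sim_params()].
#' @param noise List with per-neuron currents `I_ex` (length `n_ex`) and
#'   `I_inh` (length `n_inh`). If `NULL`, currents are drawn from the
#'   configured Gaussians using the current RNG state.
#' @return The updated state (`t` advanced by `dt`).
#' @export
step_voltages <- function(state, params, noise = NULL) {
  if (is.null(noise)) noise <- draw_noise(params)
  stopifnot(length(noise$I_ex) == length(state$v_ex),
            length(noise$I_inh) == length(state$v_inh))
  dt <- params$dt
  k1 <- rate_derivs(state$v_ex, state$v_inh, state, params,
                    noise$I_ex, noise$I_inh)
  k2 <- rate_derivs(state$v_ex + dt / 2 * k1$dve,
                    state$v_inh + dt / 2 * k1$dvi,
                    state, params, noise$I_ex, noise$I_inh)
  k3 <- rate_derivs(state$v_ex + dt / 2 * k2$dve,
                    state$v_inh + dt / 2 * k2$dvi,
                    state, params, noise$I_ex, noise$I_inh)
  k4 <- rate_derivs(state$v_ex + dt * k3$dve,
                    state$v_inh + dt * k3$dvi,
                    state, params, noise$I_ex, noise$I_inh)
  state$v_ex <- state$v_ex +
    dt / 6 * (k1$dve + 2 * k2$dve + 2 * k3$dve + k4$dve)
  state$v_inh <- state$v_inh +
    dt / 6 * (k1$dvi + 2 * k2$dvi + 2 * k3$dvi + k4$dvi)
  if (!all(is.finite(state$v_ex)) || !all(is.finite(state$v_inh)) ||
      max(abs(state$v_ex)) > 1e9 || max(abs(state$v_inh)) > 1e9) {
    bad <- which(!is.finite(state$v_ex) | abs(state$v_ex) > 1e9)
    if (!length(bad)) bad <- NA_integer_
    stop(errorCondition(
      sprintf("numerical divergence at t = %g ms (excitatory neuron %s)",
              state$t + dt, paste(bad[1], collapse = "")),
      class = c("assimnet_divergence", "error", "condition"),
      time = state$t + dt, neuron = bad[1]))
  }
  state$t <- state$t + dt
  state
}

draw_noise <- function(params) {
  sd_ex <- params$noise_ex_sd
  sd_inh <- params$noise_inh_sd
  if (isTRUE(params$white_noise_scaling)) {
    sd_ex <- sd_ex * sqrt(params$tau_ex / params$dt)
    sd_inh <- sd_inh * sqrt(params$tau_inh / params$dt)
  }
  list(I_ex = stats::rnorm(params$n_ex, params$noise_ex_mean, sd_ex),
       I_inh = stats::rnorm(params$n_inh, params$noise_inh_mean, sd_inh))
}

#' Advance the plastic weights by one Euler step of the BCM rule
#'
#' Updates every plastic excitatory-to-excitatory weight by
#' `dw = (dt / tau_w) * (-w + alpha * phi(v_post, theta) * sigma(v_pre))`,
#' where `phi` is the BCM curve ([bcm_phi()]) evaluated at the postsynaptic
#' neuron's sliding threshold and `sigma` is the presynaptic sigmoid
#' ([presyn_effect()]). The sliding-threshold estimates are updated first
#' (EMA of the postsynaptic voltage, see [update_threshold()]). Weights are
#' clamped at zero from below (excitatory synapses). Synaptic scaling is
#' *not* applied here; call [apply_synaptic_scaling()] afterwards.
#'
#' @param state A [net_state()].
#' @param params A [sim_params()].
#' @param update_theta Logical; update the sliding-threshold estimates
#'   before computing `phi` (default). Set `FALSE` to freeze `theta`, e.g.
#'   for fixed-point analyses.
#' @return The updated state.
#' @export
step_weights <- function(state, params, update_theta = TRUE) {
  if (update_theta) {
    state$n_updates <- state$n_updates + 1L
    up <- update_threshold(state$theta_hat, state$v_ex, params,
                           n_updates = state$n_updates)
    state$theta_hat <- up$theta_hat
    theta <- up$theta
  } else {
    theta <- state$theta_hat
  }
  theta <- pmax(theta, 1e-6)   # guard transiently nonpositive estimates
  phi <- bcm_phi(state$v_ex, theta)
  sigma <- presyn_effect(state$v_ex, params$beta, params$theta_act,
                         params$sigma_convention)
  dW <- (params$dt / params$tau_w) *
    (-state$W + params$alpha * outer(phi, sigma)) * state$A
  state$W <- pmax(state$W + dW, 0)
  state
}

#' Apply synaptic scaling
#'
#' Homeostatic multiplicative renormalization: for each excitatory neuron
#' the incoming plastic weights are multiplied by `kappa / sum(incoming)`,
#' so that after the operation every scaled neuron's incoming sum equals
#' `kappa`. Neurons with no incoming plastic edges are untouched; neurons
#' whose incoming sum is not positive are skipped for this step (degenerate
#' case) and counted in the `n_degenerate` attribute of the result.
#'
#' @param state A [net_state()].
#' @param params A [sim_params()].
#' @return The updated state, with attribute `n_degenerate` giving the
#'   number of skipped neurons.
#' @export
apply_synaptic_scaling <- function(state, params) {
  indeg <- rowSums(state$A)
  s <- rowSums(state$W)
  scalable <- indeg > 0 & s > 0
  degenerate <- indeg > 0 & s <= 0
  if (any(degenerate)) {
    warning(sprintf("synaptic scaling skipped for %d neuron(s) with nonpositive incoming sum",
                    sum(degenerate)))
  }
  state$W[scalable, ] <- state$W[scalable, , drop = FALSE] *
    (params$kappa / s[scalable])
  attr(state, "n_degenerate") <- sum(degenerate)
  state
}
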