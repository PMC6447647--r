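#' Simulation parameters for the plastic excitatory/inhibitory rate network
#'
#' Bundles every constant of the network model: population sizes, connection
#' probabilities, membrane and weight time constants, the threshold-linear
#' activation threshold, the BCM plasticity constants, the synaptic-scaling
#' target, the sliding-threshold averaging rate, the integration step and the
#' noise-current distributions. Defaults are the reference configuration used
#' throughout the package: a 400-excitatory / 100-inhibitory network with 20%
#' connectivity, `tau_ex = tau_inh = 20` ms, `tau_w = 1000` ms, activation
#' threshold `Theta = 1`, BCM gain `alpha = 0.1`, presynaptic sigmoid slope
#' `beta = 5`, scaling target `kappa = 0.5`, fixed inhibitory-to-excitatory
#' weight `-0.025`, fixed excitatory-to-inhibitory weight `0.2`, `dt = 0.5`
#' ms, excitatory noise current N(1, 0.5^2) and inhibitory noise N(0, 0.5^2).
#'
#' @param n_ex,n_inh Number of excitatory / inhibitory neurons (>= 1).
#' @param p_ee Connection probability between excitatory neurons. Pairs are
#'   drawn as unordered pairs and expanded reciprocally, so the excitatory
#'   adjacency matrix is symmetric.
#' @param p_ei Probability of an inhibitory-to-excitatory connection.
#' @param p_ie Probability of an excitatory-to-inhibitory connection.
#' @param tau_ex,tau_inh,tau_w Membrane and weight time constants (ms).
#' @param theta_act Activation threshold `Theta` of the threshold-linear
#'   rate function.
#' @param alpha BCM plasticity gain.
#' @param beta Slope of the presynaptic sigmoid.
#' @param kappa Synaptic-scaling target: total incoming plastic weight per
#'   excitatory neuron after scaling.
#' @param gamma Sliding-threshold averaging rate (1/ms). The BCM threshold
#'   estimate is an exponential moving average of the postsynaptic voltage
#'   with per-step rate `gamma * dt`; `1/gamma` is the averaging window.
#' @param dt Integration step (ms) for both the RK4 voltage update and the
#'   Euler weight update.
#' @param w_ei_fixed Fixed weight of inhibitory-to-excitatory synapses
#'   (negative: inhibition).
#' @param w_ie_fixed Fixed weight of excitatory-to-inhibitory synapses.
#' @param noise_ex_mean,noise_ex_sd Mean / sd of the excitatory noise current.
#' @param noise_inh_mean,noise_inh_sd Mean / sd of the inhibitory noise
#'   current.
#' @param sigma_convention Argument convention of the presynaptic sigmoid:
#'   `"centered"` uses `beta * (v - theta_act)` (midpoint 0.5 at threshold),
#'   `"literal"` uses `beta * v + theta_act`. See [presyn_effect()].
#' @param bias_correct_theta Logical; apply the finite-horizon bias
#'   correction to the sliding-threshold moving average (see
#'   [update_threshold()]).
#' @param white_noise_scaling Logical; if `TRUE` the printed noise sd is
#'   interpreted as a white-noise density and multiplied by `sqrt(tau/dt)`
#'   per step. Default `FALSE`: the sd is used per step as printed.
#' @param noise_redraw_every Number of integration steps between redraws of
#'   the noise currents, i.e. the noise correlation time in units of `dt`.
#'   1 (default) redraws every step; `Inf` freezes a single draw per neuron
#'   for the whole run (quenched heterogeneous tonic drive).
#' @param scaling_every Number of integration steps between applications of
#'   synaptic scaling. 1 (default) rescales after every weight update;
#'   0 disables scaling (the sliding BCM threshold alone then bounds the
#'   weight dynamics).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [build_topology()], [run_simulation()]
#' @export
#' @examples
#' p <- sim_params(n_ex = 40, n_inh = 10)
#' p$kappa
sim_params <- function(n_ex = 400L, n_inh = 100L,
                       p_ee = 0.2, p_ei = 0.2, p_ie = 0.2,
                       tau_ex = 20.0, tau_inh = 20.0, tau_w = 1000.0,
                       theta_act = 1.0, alpha = 0.1, beta = 5.0,
                       kappa = 0.5, gamma = 0.001, dt = 0.5,
                       w_ei_fixed = -0.025, w_ie_fixed = 0.2,
                       noise_ex_mean = 1.0, noise_ex_sd = 0.5,
                       noise_inh_mean = 0.0, noise_inh_sd = 0.5,
                       sigma_convention = c("centered", "literal"),
                       bias_correct_theta = FALSE,
                       white_noise_scaling = FALSE,
                       noise_redraw_every = 1,
                       scaling_every = 1L) {
  sigma_convention <- match.arg(sigma_convention)
  p <- list(
    n_ex = as.integer(n_ex), n_inh = as.integer(n_inh),
    p_ee = p_ee, p_ei = p_ei, p_ie = p_ie,
    tau_ex = tau_ex, tau_inh = tau_inh, tau_w = tau_w,
    theta_act = theta_act, alpha = alpha, beta = beta,
    kappa = kappa, gamma = gamma, dt = dt,
    w_ei_fixed = w_ei_fixed, w_ie_fixed = w_ie_fixed,
    noise_ex_mean = noise_ex_mean, noise_ex_sd = noise_ex_sd,
    noise_inh_mean = noise_inh_mean, noise_inh_sd = noise_inh_sd,
    sigma_convention = sigma_convention,
    bias_correct_theta = isTRUE(bias_correct_theta),
    white_noise_scaling = isTRUE(white_noise_scaling),
    noise_redraw_every = noise_redraw_every,
    scaling_every = as.integer(scaling_every)
  )
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_ex >= 1L, p$n_inh >= 1L,
    p$tau_ex > 0, p$tau_inh > 0, p$tau_w > 0, p$dt > 0,
    p$noise_ex_sd >= 0, p$noise_inh_sd >= 0,
    p$kappa > 0, p$gamma >= 0
  )
  for (pr in c("p_ee", "p_ei", "p_ie")) {
    if (p[[pr]] < 0 || p[[pr]] > 1) {
      stop(sprintf("connection probability `%s` must be in [0, 1]", pr),
           call. = FALSE)
    }
  }
  if (p$gamma * p$dt >= 1) {
    stop("unstable threshold averaging: gamma * dt must be < 1", call. = FALSE)
  }
  if (!(p$noise_redraw_every >= 1)) {
    stop("noise_redraw_every must be >= 1 (or Inf)", call. = FALSE)
  }
  if (is.na(p$scaling_every) || p$scaling_every < 0L) {
    stop("scaling_every must be a nonnegative integer", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d excitatory + %d inhibitory neurons\n",
              x$n_ex, x$n_inh))
  cat(sprintf("  P(E<-E) = %g (reciprocal), P(E<-I) = %g, P(I<-E) = %g\n",
              x$p_ee, x$p_ei, x$p_ie))
  cat(sprintf("  tau_ex = %g ms, tau_inh = %g ms, tau_w = %g ms, dt = %g ms\n",
              x$tau_ex, x$tau_inh, x$tau_w, x$dt))
  cat(sprintf("  Theta = %g, alpha = %g, beta = %g (%s), kappa = %g, gamma = %g /ms\n",
              x$theta_act, x$alpha, x$beta, x$sigma_convention, x$kappa,
              x$gamma))
  cat(sprintf("  I_ex ~ N(%g, %g^2), I_inh ~ N(%g, %g^2)%s\n",
              x$noise_ex_mean, x$noise_ex_sd, x$noise_inh_mean, x$noise_inh_sd,
              if (x$white_noise_scaling) " [white-noise scaled]" else ""))
  invisible(x)
}
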