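#' Threshold-linear activation function
#'
#' Converts a membrane voltage into a firing rate: `F(v) = v` for
#' `v >= theta_act` and 0 below threshold. Vectorized over `v`.
#'
#' @param v Voltage(s).
#' @param theta_act Activation threshold.
#' @return Rate(s), same length as `v`.
#' @export
#' @examples
#' activation(c(0.5, 1, 2.3), theta_act = 1)
activation <- function(v, theta_act = 1.0) {
  ifelse(v >= theta_act, v, 0)
}

#' Presynaptic effect (sigmoid of presynaptic voltage)
#'
#' Logistic gating of the BCM weight update by the presynaptic voltage,
#' strictly increasing with range (0, 1). Two argument conventions are
#' supported: `"centered"` evaluates `1 / (1 + exp(-beta * (v - theta_act)))`,
#' which puts the midpoint 0.5 at the activation threshold; `"literal"`
#' evaluates `1 / (1 + exp(-(beta * v + theta_act)))`.
#'
#' @param v Presynaptic voltage(s).
#' @param beta Sigmoid slope.
#' @param theta_act Activation threshold.
#' @param convention `"centered"` (default) or `"literal"`.
#' @return Value(s) in (0, 1).
#' @export
#' @examples
#' presyn_effect(1, beta = 5, theta_act = 1)            # 0.5 at threshold
#' presyn_effect(0, beta = 5, theta_act = 1, convention = "literal")
presyn_effect <- function(v, beta = 5.0, theta_act = 1.0,
                          convention = c("centered", "literal")) {
  convention <- match.arg(convention)
  x <- if (convention == "centered") beta * (v - theta_act) else beta * v + theta_act
  1 / (1 + exp(-x))
}

#' BCM postsynaptic effect
#'
#' The Bienenstock-Cooper-Munro curve
#' `phi(v, theta) = 6.75 v^2 (v - theta) / theta^3 + tanh(6.75 (v - theta) / theta)`:
#' zero at `v = theta` (and near `v = 0`), negative (depression) for
#' `0 < v < theta`, positive (potentiation) for `v > theta`. `theta` is the
#' sliding modification threshold.
#'
#' @param v Postsynaptic voltage(s).
#' @param theta Sliding BCM threshold (> 0).
#' @return Weight-change drive, same length as `v`.
#' @export
#' @examples
#' bcm_phi(1, 1)        # 0 at the threshold
#' bcm_phi(2, 1)        # 27 + tanh(6.75)
bcm_phi <- function(v, theta) {
  if (any(theta <= 0)) {
    stop("invalid BCM threshold: theta must be > 0", call. = FALSE)
  }
  6.75 * v^2 * (v - theta) / theta^3 + tanh(6.75 * (v - theta) / theta)
}

#' Update the sliding BCM threshold estimate
#'
#' The modification threshold tracks the temporal mean of the postsynaptic
#' voltage through an exponential moving average with per-step rate
#' `gamma * dt`:
#' `theta_hat <- (1 - gamma dt) theta_hat + gamma dt v`. Under stationary
#' dynamics the estimate converges to the mean voltage. With
#' `bias_correct = TRUE` the effective threshold divides out the finite
#' horizon: `theta = theta_hat_corrected` with
#' `theta_hat / (1 - (1 - gamma dt)^n)` after `n` updates starting from 0
#' (Adam-style correction); by default the plain estimate is used.
#'
#' @param theta_hat Current estimate(s).
#' @param v_post Postsynaptic voltage(s).
#' @param params A [sim_params()] object (uses `gamma`, `dt`,
#'   `bias_correct_theta`).
#' @param n_updates Number of EMA updates performed so far *including* this
#'   one; only used for the bias correction.
#' @return List with `theta_hat` (updated estimate) and `theta` (effective
#'   threshold used by the BCM curve).
#' @export
#' @examples
#' p <- sim_params(n_ex = 1, n_inh = 1, gamma = 0.2, dt = 0.5)
#' update_threshold(0, 1, p)$theta_hat   # one plain EMA step: 0.1
update_threshold <- function(theta_hat, v_post, params, n_updates = NULL) {
  r <- params$gamma * params$dt
  if (r >= 1) stop("unstable threshold averaging: gamma * dt must be < 1",
                   call. = FALSE)
  theta_hat <- (1 - r) * theta_hat + r * v_post
  theta <- theta_hat
  if (isTRUE(params$bias_correct_theta)) {
    if (is.null(n_updates)) {
      stop("bias correction requires `n_updates`", call. = FALSE)
    }
    denom <- 1 - (1 - r)^n_updates
    if (denom > 0) theta <- theta_hat / denom
  }
  list(theta_hat = theta_hat, theta = theta)
}
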