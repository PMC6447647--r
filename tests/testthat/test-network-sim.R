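test_that("topology has the exact reciprocal edge count and no self-edges", {
  p <- sim_params(n_ex = 400L, n_inh = 100L)
  set.seed(11)
  topo <- build_topology(p)
  expect_equal(nrow(topo$ee), 2 * round(0.2 * 400 * 399 / 2))  # 31,920
  expect_true(all(topo$ee[, "post"] != topo$ee[, "pre"]))
  a <- ee_adjacency(topo)
  expect_identical(a, t(a))

  empty <- build_topology(sim_params(n_ex = 20L, n_inh = 5L, p_ee = 0))
  expect_identical(nrow(empty$ee), 0L)
  full <- build_topology(sim_params(n_ex = 10L, n_inh = 2L, p_ee = 1))
  expect_equal(nrow(full$ee), 10 * 9)
})

test_that("topology E-I edge counts follow their Bernoulli probabilities", {
  p <- sim_params(n_ex = 200L, n_inh = 50L, p_ie = 0.3, p_ei = 0.1)
  set.seed(5)
  topo <- build_topology(p)
  # binomial counts within 5 sd
  expect_lt(abs(nrow(topo$ie) - 0.3 * 200 * 50),
            5 * sqrt(200 * 50 * 0.3 * 0.7))
  expect_lt(abs(nrow(topo$ei) - 0.1 * 200 * 50),
            5 * sqrt(200 * 50 * 0.1 * 0.9))
})

test_that("activation is threshold-linear with boundary at the threshold", {
  expect_identical(activation(0.5, 1), 0)
  expect_identical(activation(1, 1), 1)
  expect_identical(activation(2.3, 1), 2.3)
  expect_equal(activation(c(-1, 0.99, 1.01), 1), c(0, 0, 1.01))
})

test_that("presynaptic sigmoid honours both conventions and is increasing", {
  expect_equal(presyn_effect(1, beta = 5, theta_act = 1), 0.5)
  expect_equal(presyn_effect(0, beta = 5, theta_act = 1,
                             convention = "literal"),
               1 / (1 + exp(-1)))
  expect_equal(presyn_effect(50, 5, 1), 1, tolerance = 1e-12)
  expect_equal(presyn_effect(-50, 5, 1), 0, tolerance = 1e-12)
  v <- seq(-2, 3, by = 0.05)
  for (conv in c("centered", "literal")) {
    s <- presyn_effect(v, 5, 1, conv)
    expect_true(all(diff(s) > 0))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("BCM curve matches analytic values and sign structure", {
  for (th in c(0.3, 1, 2.5)) {
    expect_equal(bcm_phi(th, th), 0)
    expect_equal(bcm_phi(2 * th, th), 27 + tanh(6.75))
  }
  expect_equal(bcm_phi(0, 1), tanh(-6.75))
  th <- 0.8
  v_below <- seq(0.05, th - 0.01, by = 0.01)
  v_above <- seq(th + 0.01, 4, by = 0.05)
  expect_true(all(bcm_phi(v_below, th) < 0))
  expect_true(all(bcm_phi(v_above, th) > 0))
  expect_error(bcm_phi(1, 0), "theta")
})

test_that("sliding threshold is an EMA converging to the stationary mean", {
  p <- sim_params(n_ex = 1L, n_inh = 1L, gamma = 0.2, dt = 0.5)
  expect_equal(update_threshold(0, 1, p)$theta_hat, 0.1)

  p0 <- sim_params(n_ex = 1L, n_inh = 1L, gamma = 0)
  expect_equal(update_threshold(0.7, 5, p0)$theta_hat, 0.7)

  th <- 0
  pg <- sim_params(n_ex = 1L, n_inh = 1L, gamma = 0.01, dt = 0.5)
  for (i in 1:5000) th <- update_threshold(th, 1.2, pg)$theta_hat
  expect_equal(th, 1.2, tolerance = 1e-6)

  expect_error(sim_params(gamma = 3, dt = 0.5), "unstable")
})

test_that("bias-corrected threshold removes the cold-start transient", {
  p <- sim_params(n_ex = 1L, n_inh = 1L, gamma = 0.01, dt = 0.5,
                  bias_correct_theta = TRUE)
  th <- 0
  for (i in 1:10) {
    up <- update_threshold(th, 2, p, n_updates = i)
    th <- up$theta_hat
  }
  # corrected estimate of a constant signal is exact from the first step
  expect_equal(up$theta, 2, tolerance = 1e-12)
})

test_that("RK4 integration matches the closed-form single-neuron solution", {
  cur <- 1.7
  tau <- 20
  p <- isolated_params(cur, dt = 0.5, tau = tau)
  set.seed(1)
  topo <- build_topology(p)
  rec <- run_simulation(p, topo, t_end = 100, record_every = 1)
  exact <- cur * (1 - exp(-rec$times / tau))
  expect_lt(max(abs(rec$v_ex[, 1] - exact)), 1e-8)

  # fourth-order convergence: halving dt shrinks the error ~16x
  err_at <- function(dt) {
    pp <- isolated_params(cur, dt = dt, tau = tau)
    r <- run_simulation(pp, build_topology(pp), t_end = 20,
                        record_every = 1)
    max(abs(r$v_ex[, 1] - cur * (1 - exp(-r$times / tau))))
  }
  ratio <- err_at(2) / err_at(1)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("zero initial state with no drive is a fixed point", {
  p <- isolated_params(0)
  rec <- run_simulation(p, build_topology(p), t_end = 50, record_every = 1)
  expect_true(all(rec$v_ex == 0))
})

test_that("inhibition lowers the excitatory drive", {
  # one E neuron receiving one I neuron clamped above threshold by its noise
  p <- sim_params(n_ex = 1L, n_inh = 1L, p_ee = 0, p_ei = 1, p_ie = 0,
                  noise_ex_mean = 1, noise_ex_sd = 0,
                  noise_inh_mean = 3, noise_inh_sd = 0)
  p0 <- p
  p0$w_ei_fixed <- 0
  topo <- build_topology(p)
  v_with <- run_simulation(p, topo, t_end = 200)$final_state$v_ex
  v_without <- run_simulation(p0, topo, t_end = 200)$final_state$v_ex
  expect_lt(v_with, v_without)
})

test_that("pure weight decay (alpha = 0) is monotone and scaling preserves ratios", {
  p <- tiny_params(alpha = 0)
  set.seed(8)
  topo <- build_topology(p)
  st <- net_state(p, topo)
  st$v_ex <- runif(p$n_ex, 0.5, 1.5)
  w0 <- st$W[st$A > 0]
  st1 <- step_weights(st, p)
  w1 <- st1$W[st1$A > 0]
  expect_true(all(w1 < w0))               # uniform decay toward 0
  st2 <- apply_synaptic_scaling(st1, p)
  # decay is multiplicative, so scaling restores the original weights
  expect_equal(st2$W, st$W, tolerance = 1e-12)
})

test_that("frozen-voltage Euler iteration converges to the BCM fixed point", {
  p <- sim_params(n_ex = 2L, n_inh = 1L, p_ee = 1, p_ei = 0, p_ie = 0,
                  tau_w = 50)
  topo <- build_topology(p)
  st <- net_state(p, topo)
  st$v_ex <- c(1.6, 1.4)
  st$theta_hat <- c(1, 1)
  for (i in 1:3000) st <- step_weights(st, p, update_theta = FALSE)
  sigma <- presyn_effect(st$v_ex, p$beta, p$theta_act)
  phi <- bcm_phi(st$v_ex, st$theta_hat)
  w_star <- p$alpha * outer(phi, sigma)
  expect_equal(st$W[1, 2], w_star[1, 2], tolerance = 1e-6)
  expect_equal(st$W[2, 1], w_star[2, 1], tolerance = 1e-6)
  # v_post at threshold: phi = 0, pure decay of that edge
  st$theta_hat <- st$v_ex
  st3 <- step_weights(st, p, update_theta = FALSE)
  expect_equal(st3$W[1, 2], st$W[1, 2] * (1 - p$dt / p$tau_w))
})

test_that("synaptic scaling renormalizes incoming sums to kappa", {
  p <- sim_params(n_ex = 4L, n_inh = 1L, p_ee = 0, kappa = 0.5)
  topo <- build_topology(p)
  topo$ee <- cbind(post = c(1L, 1L, 1L, 2L, 4L),
                   pre = c(2L, 3L, 4L, 1L, 1L))
  st <- net_state(p, topo)
  st$W[1, c(2, 3, 4)] <- c(0.2, 0.3, 0.5)
  st$W[2, 1] <- 0.5
  st$W[4, 1] <- 0
  expect_warning(st2 <- apply_synaptic_scaling(st, p), "skip")
  expect_equal(st2$W[1, c(2, 3, 4)], c(0.1, 0.15, 0.25))
  expect_equal(st2$W[2, 1], 0.5)       # already at kappa: unchanged
  expect_equal(st2$W[4, 1], 0)         # degenerate neuron skipped
  expect_identical(attr(st2, "n_degenerate"), 1L)
  sums <- rowSums(st2$W)[c(1, 2)]
  expect_equal(unname(sums), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("compiled and reference engines agree step for step", {
  p <- tiny_params()
  set.seed(42)
  topo <- build_topology(p)
  ev <- list(list(time = 5, members = c(1L, 2L, 3L)))
  re <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L))
  r_cpp <- run_simulation(p, topo, t_end = 25, events = ev,
                          record_every = 1, record_edges = re,
                          engine = "cpp", seed = 7)
  r_ref <- run_simulation(p, topo, t_end = 25, events = ev,
                          record_every = 1, record_edges = re,
                          engine = "r", seed = 7)
  expect_equal(r_cpp$v_ex, r_ref$v_ex, tolerance = 1e-10)
  expect_equal(r_cpp$w, r_ref$w, tolerance = 1e-10)
  expect_equal(r_cpp$final_state$theta_hat, r_ref$final_state$theta_hat,
               tolerance = 1e-10)
})

test_that("identical seeds give identical recordings; t_end = 0 is a no-op", {
  p <- tiny_params()
  set.seed(2)
  topo <- build_topology(p)
  r1 <- run_simulation(p, topo, t_end = 100, seed = 9)
  r2 <- run_simulation(p, topo, t_end = 100, seed = 9)
  expect_identical(r1$v_ex, r2$v_ex)
  expect_identical(r1$final_state$w, r2$final_state$w)

  r0 <- run_simulation(p, topo, t_end = 0, seed = 9)
  expect_identical(r0$times, 0)
  expect_true(all(r0$v_ex == 0))
})

test_that("reciprocity survives assembly insertion and weights start at zero", {
  # deterministic drive keeps the voltages supra-threshold so that the
  # BCM term potentiates the freshly inserted edges
  p <- tiny_params(p_ei = 0, p_ie = 0, noise_ex_sd = 0, noise_ex_mean = 1.5,
                   noise_inh_sd = 0)
  set.seed(3)
  topo <- build_topology(p)
  members <- c(4L, 9L, 17L)
  ev <- list(list(time = 10, members = members))
  rec <- run_simulation(p, topo, t_end = 200, events = ev,
                        record_every = 1,
                        record_edges = assimnet:::assembly_edges(members))
  w <- rec$final_state$w
  key <- paste(w$post, w$pre)
  expect_true(all(paste(w$pre, w$post) %in% key))  # symmetric edge set
  # inserted edges are zero up to and including the insertion-time sample
  added <- rec$events[[1]]$added_edges
  expect_gt(nrow(added), 0)
  pre_rows <- rec$times <= 10
  pos <- match(paste(added[, 1], added[, 2]),
               paste(rec$record_edges[, 1], rec$record_edges[, 2]))
  expect_true(all(rec$w[pre_rows, pos] == 0))
  expect_true(any(rec$w[!pre_rows, pos] > 0))
})

test_that("numerical divergence raises a condition carrying the partial recording", {
  p <- sim_params(n_ex = 2L, n_inh = 1L, p_ee = 1, p_ei = 0, p_ie = 0,
                  kappa = 50, noise_ex_mean = 5, noise_ex_sd = 0)
  topo <- build_topology(p)
  err <- tryCatch(run_simulation(p, topo, t_end = 500, record_every = 1),
                  assimnet_divergence = function(e) e)
  expect_s3_class(err, "assimnet_divergence")
  expect_s3_class(err$recording, "net_recording")
  expect_gt(length(err$recording$times), 1)
  expect_true(is.finite(err$time))
})

test_that("default-parameter network sustains irregular near-threshold activity", {
  p <- sim_params()
  set.seed(21)
  topo <- build_topology(p)
  rec <- run_simulation(p, topo, t_end = 15000, seed = 21)
  af <- activity_fraction(rec, window_ms = 5000)
  expect_true(all(af$active_fraction > 0))
  expect_true(all(af$active_fraction < 1))
  expect_lt(rec$max_scaling_dev, 1e-10)
  expect_identical(rec$n_degenerate, 0)
})
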