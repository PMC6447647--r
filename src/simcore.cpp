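#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Threshold-linear rate function
static inline double act(double v, double theta) {
  return v >= theta ? v : 0.0;
}

static inline double sigmoid_pre(double v, double beta, double theta_act,
                                 int centered) {
  double x = centered ? beta * (v - theta_act) : beta * v + theta_act;
  return 1.0 / (1.0 + std::exp(-x));
}

static inline double bcm(double v, double th) {
  return 6.75 * v * v * (v - th) / (th * th * th)
       + std::tanh(6.75 * (v - th) / th);
}

// Full simulation loop: RK4 voltage integration, EMA sliding threshold,
// Euler BCM weight update, synaptic scaling, scheduled edge activation,
// periodic recording. Connectivity is passed CSR-grouped by postsynaptic
// neuron; `ee_active` holds the step index from which each plastic edge
// participates (0 = from the start; later values implement cell-assembly
// insertion: the edge sits at weight zero and is skipped by plasticity
// until its activation step). All indices are 0-based.
// [[Rcpp::export]]
List sim_core(int n_ex, int n_inh,
              IntegerVector ee_row_ptr, IntegerVector ee_col,
              NumericVector ee_w0, IntegerVector ee_active,
              IntegerVector ei_row_ptr, IntegerVector ei_col,
              IntegerVector ie_row_ptr, IntegerVector ie_col,
              List pars, int n_steps, int record_every,
              IntegerVector rec_pos,
              NumericVector v_ex0, NumericVector v_inh0,
              NumericVector theta0) {
  const double tau_ex = pars["tau_ex"], tau_inh = pars["tau_inh"],
               tau_w = pars["tau_w"], theta_act = pars["theta_act"],
               alpha = pars["alpha"], beta = pars["beta"],
               kappa = pars["kappa"], gamma = pars["gamma"],
               dt = pars["dt"], w_ei = pars["w_ei_fixed"],
               w_ie = pars["w_ie_fixed"],
               nem = pars["noise_ex_mean"], nim = pars["noise_inh_mean"];
  double nes = pars["noise_ex_sd"], nis = pars["noise_inh_sd"];
  const int centered = as<int>(pars["sigma_centered"]);
  const double redraw_raw = as<double>(pars["noise_redraw_every"]);
  const long long redraw =
      R_FINITE(redraw_raw) ? (long long)(redraw_raw + 0.5) : 0LL;  // 0 = never
  const bool bias = as<bool>(pars["bias_correct_theta"]);
  const int scaling_every = as<int>(pars["scaling_every"]);
  if (as<bool>(pars["white_noise_scaling"])) {
    nes *= std::sqrt(tau_ex / dt);
    nis *= std::sqrt(tau_inh / dt);
  }
  const double r = gamma * dt;
  const int ne = ee_w0.size();
  const int n_rec = rec_pos.size();

  std::vector<double> w(ee_w0.begin(), ee_w0.end());
  std::vector<double> vex(v_ex0.begin(), v_ex0.end());
  std::vector<double> vinh(v_inh0.begin(), v_inh0.end());
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> Fex(n_ex), Finh(n_inh),
      k1e(n_ex), k2e(n_ex), k3e(n_ex), k4e(n_ex),
      k1i(n_inh), k2i(n_inh), k3i(n_inh), k4i(n_inh),
      te(n_ex), ti(n_inh), Iex(n_ex), Iinh(n_inh),
      phi(n_ex), sig(n_ex);

  const int n_samp_max = n_steps / record_every + 1;
  NumericMatrix v_trace(n_samp_max, n_ex);
  NumericMatrix w_trace(n_samp_max, n_rec > 0 ? n_rec : 1);
  IntegerVector sample_steps(n_samp_max);

  long long n_degenerate = 0;
  double max_scaling_dev = 0.0;
  bool diverged = false;
  int div_step = -1, div_neuron = -1;

  auto deriv = [&](const std::vector<double>& ve,
                   const std::vector<double>& vi,
                   std::vector<double>& de, std::vector<double>& di) {
    for (int j = 0; j < n_ex; ++j) Fex[j] = act(ve[j], theta_act);
    for (int j = 0; j < n_inh; ++j) Finh[j] = act(vi[j], theta_act);
    for (int i = 0; i < n_ex; ++i) {
      double s = 0.0;
      for (int k = ee_row_ptr[i]; k < ee_row_ptr[i + 1]; ++k)
        s += w[k] * Fex[ee_col[k]];
      double si = 0.0;
      for (int k = ei_row_ptr[i]; k < ei_row_ptr[i + 1]; ++k)
        si += Finh[ei_col[k]];
      de[i] = (-ve[i] + s + w_ei * si + Iex[i]) / tau_ex;
    }
    for (int i = 0; i < n_inh; ++i) {
      double s = 0.0;
      for (int k = ie_row_ptr[i]; k < ie_row_ptr[i + 1]; ++k)
        s += Fex[ie_col[k]];
      di[i] = (-vi[i] + w_ie * s + Iinh[i]) / tau_inh;
    }
  };

  auto record = [&](int row, int step) {
    sample_steps[row] = step;
    for (int j = 0; j < n_ex; ++j) v_trace(row, j) = vex[j];
    for (int m = 0; m < n_rec; ++m) w_trace(row, m) = w[rec_pos[m]];
  };

  record(0, 0);
  int n_samples = 1;

  for (int s = 0; s < n_steps; ++s) {
    // one noise draw per neuron per redraw interval (default: every
    // step), frozen across the RK4 stages
    if (s == 0 || (redraw > 0 && s % redraw == 0)) {
      for (int i = 0; i < n_ex; ++i) Iex[i] = R::rnorm(nem, nes);
      for (int i = 0; i < n_inh; ++i) Iinh[i] = R::rnorm(nim, nis);
    }

    deriv(vex, vinh, k1e, k1i);
    for (int i = 0; i < n_ex; ++i) te[i] = vex[i] + 0.5 * dt * k1e[i];
    for (int i = 0; i < n_inh; ++i) ti[i] = vinh[i] + 0.5 * dt * k1i[i];
    deriv(te, ti, k2e, k2i);
    for (int i = 0; i < n_ex; ++i) te[i] = vex[i] + 0.5 * dt * k2e[i];
    for (int i = 0; i < n_inh; ++i) ti[i] = vinh[i] + 0.5 * dt * k2i[i];
    deriv(te, ti, k3e, k3i);
    for (int i = 0; i < n_ex; ++i) te[i] = vex[i] + dt * k3e[i];
    for (int i = 0; i < n_inh; ++i) ti[i] = vinh[i] + dt * k3i[i];
    deriv(te, ti, k4e, k4i);
    for (int i = 0; i < n_ex; ++i)
      vex[i] += dt / 6.0 * (k1e[i] + 2.0 * k2e[i] + 2.0 * k3e[i] + k4e[i]);
    for (int i = 0; i < n_inh; ++i)
      vinh[i] += dt / 6.0 * (k1i[i] + 2.0 * k2i[i] + 2.0 * k3i[i] + k4i[i]);

    for (int i = 0; i < n_ex && !diverged; ++i)
      if (!std::isfinite(vex[i]) || std::fabs(vex[i]) > 1e9) {
        diverged = true; div_step = s + 1; div_neuron = i + 1;
      }
    for (int i = 0; i < n_inh && !diverged; ++i)
      if (!std::isfinite(vinh[i]) || std::fabs(vinh[i]) > 1e9) {
        diverged = true; div_step = s + 1; div_neuron = -(i + 1);
      }
    if (diverged) break;

    // sliding threshold (EMA of postsynaptic voltage), BCM drives
    const double bias_denom = bias ? 1.0 - std::pow(1.0 - r, s + 1) : 1.0;
    for (int i = 0; i < n_ex; ++i) {
      th[i] = (1.0 - r) * th[i] + r * vex[i];
      double theta_eff = (bias && bias_denom > 0) ? th[i] / bias_denom : th[i];
      if (theta_eff < 1e-6) theta_eff = 1e-6;
      phi[i] = bcm(vex[i], theta_eff);
      sig[i] = sigmoid_pre(vex[i], beta, theta_act, centered);
    }

    // Euler BCM update with clamping, then multiplicative scaling
    for (int i = 0; i < n_ex; ++i) {
      const int k0 = ee_row_ptr[i], k1 = ee_row_ptr[i + 1];
      int n_act = 0;
      for (int k = k0; k < k1; ++k) {
        if (ee_active[k] > s) continue;
        ++n_act;
        double wv = w[k];
        wv += (dt / tau_w) * (-wv + alpha * phi[i] * sig[ee_col[k]]);
        w[k] = wv < 0.0 ? 0.0 : wv;
      }
      if (n_act > 0 && scaling_every > 0 && (s + 1) % scaling_every == 0) {
        double sum = 0.0;
        for (int k = k0; k < k1; ++k) sum += w[k];
        if (sum > 0.0) {
          const double f = kappa / sum;
          double sum2 = 0.0;
          for (int k = k0; k < k1; ++k) { w[k] *= f; sum2 += w[k]; }
          const double dev = std::fabs(sum2 - kappa);
          if (dev > max_scaling_dev) max_scaling_dev = dev;
        } else {
          ++n_degenerate;
        }
      }
    }

    if ((s + 1) % record_every == 0) {
      record(n_samples, s + 1);
      ++n_samples;
    }
  }

  return List::create(
    _["v_trace"] = v_trace, _["w_trace"] = w_trace,
    _["sample_steps"] = sample_steps, _["n_samples"] = n_samples,
    _["v_ex_final"] = NumericVector(vex.begin(), vex.end()),
    _["v_inh_final"] = NumericVector(vinh.begin(), vinh.end()),
    _["theta_hat_final"] = NumericVector(th.begin(), th.end()),
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["n_degenerate"] = (double)n_degenerate,
    _["max_scaling_dev"] = max_scaling_dev,
    _["diverged"] = diverged, _["div_step"] = div_step,
    _["div_neuron"] = div_neuron);
}
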