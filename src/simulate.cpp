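#include <Rcpp.h>
using namespace Rcpp;

// Sequential conditional-Poisson spike generation with self-history.
// gen: generator signal without the history term (stimulus + offset + b0)
// h:   post-spike kernel values at delays 1..length(h) ms (<= 0)
// valid: bins outside the recorded trial never spike
// rate_out: filled with the realized conditional intensity (spk/s)
// Bernoulli thinning at 1 ms bins: p(spike) = min(lambda * delta, 1).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector simulate_spikes_history_cpp(NumericVector gen, NumericVector h,
                                          double rmax, double delta_s,
                                          LogicalVector valid,
                                          NumericVector rate_out) {
  int n = gen.size();
  int nh = h.size();
  IntegerVector spikes(n);
  for (int t = 0; t < n; ++t) {
    double g = gen[t];
    int lim = std::min(nh, t);
    for (int tau = 1; tau <= lim; ++tau) {
      if (spikes[t - tau]) g += h[tau - 1];
    }
    double lambda = rmax / (1.0 + std::exp(-g));
    rate_out[t] = lambda;
    if (!valid[t]) continue;
    double p = lambda * delta_s;
    if (p > 1.0) p = 1.0;
    if (unif_rand() < p) spikes[t] = 1;
  }
  return spikes;
}

// History term of the generator signal for a *given* spike train:
// out[t] = sum_tau h(tau) * r(t - tau).
// [[Rcpp::export]]
NumericVector history_filter_cpp(IntegerVector spikes, NumericVector h) {
  int n = spikes.size();
  int nh = h.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    if (spikes[t]) {
      int lim = std::min(n - 1, t + nh);
      for (int u = t + 1; u <= lim; ++u) out[u] += h[u - t - 1];
    }
  }
  return out;
}

// Stimulus drive: out[t] = sum_tau k[probe_on(t - tau), t, tau] for the
// one-probe-per-bin stimulus encoding.  kernel is an [np, nt, ntau]
// array (column-major), probe 1-based, 0 = no probe on.
// [[Rcpp::export]]
NumericVector stimulus_drive_cpp(IntegerVector probe, NumericVector kernel,
                                 int np, int nt, int ntau) {
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    double acc = 0.0;
    int lim = std::min(ntau, t);
    for (int tau = 1; tau <= lim; ++tau) {
      int p = probe[t - tau];
      if (p > 0) {
        // kernel[(p-1) + np * t + np * nt * (tau-1)]
        acc += kernel[(p - 1) + (size_t)np * t + (size_t)np * nt * (tau - 1)];
      }
    }
    out[t] = acc;
  }
  return out;
}

// Single-coefficient maximum-likelihood screen, vectorized over the
// tensor-product columns of one probe: for each (i, j) the design
// column is Ub[, i] * V[, j] and the 1-parameter model
// lambda = rmax * sigmoid(b0 + kappa * x) is fitted by Newton ascent.
// The time basis functions V[, j] have compact support, so each column
// only loops over V's nonzero rows.  Where x = 0 the model sits at the
// baseline and contributes a constant to the likelihood, so those bins
// drop out of the score exactly.
// Returns kappa-hat in column order (j - 1) * n_i + i.
// [[Rcpp::export]]
NumericVector newton_screen_cpp(NumericMatrix Ub, NumericMatrix V,
                                IntegerVector r, double b0, double rmax,
                                double delta_s, int iters) {
  int n = Ub.nrow();
  int ni = Ub.ncol();
  int nj = V.ncol();
  NumericVector kappa(ni * nj);
  std::vector<int> rows;
  rows.reserve(n);
  for (int j = 0; j < nj; ++j) {
    rows.clear();
    for (int t = 0; t < n; ++t) {
      if (V(t, j) != 0.0) rows.push_back(t);
    }
    if (rows.empty()) continue;
    for (int i = 0; i < ni; ++i) {
      double k = 0.0;
      for (int it = 0; it < iters; ++it) {
        double grad = 0.0, hess = 0.0;
        for (size_t m = 0; m < rows.size(); ++m) {
          int t = rows[m];
          double x = Ub(t, i) * V(t, j);
          if (x == 0.0) continue;
          double lam = rmax / (1.0 + std::exp(-(b0 + k * x)));
          double q = 1.0 - lam / rmax;
          double resid = r[t] - lam * delta_s;
          grad += x * resid * q;
          hess += x * x * (-q * lam * (delta_s * q + resid / rmax));
        }
        if (hess > -1e-10) hess = -1e-10;
        double step = grad / hess;
        if (step > 5.0) step = 5.0;
        if (step < -5.0) step = -5.0;
        k -= step;
        if (std::fabs(step) < 1e-8) break;
      }
      kappa[j * ni + i] = k;
    }
  }
  return kappa;
}
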