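#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a population of Izhikevich neurons coupled by
// exponentially decaying postsynaptic currents.
//
// wt       : N x N weight matrix, wt(j, i) = PSC amplitude evoked in target j
//            by a spike of source i (column i is contiguous = one source).
// is_exc   : per-neuron flag; decides which accumulator (tau_e vs tau_i) a
//            neuron's spikes feed in its targets.
// ext      : n_substeps x K matrix of shared external current channels
//            (alpha drives, stimulus); gain(n, k) mixes channel k into
//            neuron n (mostly 0/1 masks).
// Noise is drawn independently per neuron per substep from N(mu, sd), using
// R's RNG so that set.seed() upstream makes runs bit-reproducible.
//
// Spikes are detected after each substep (v >= 30 mV), the spike time is the
// end of that substep (time of peak, before reset), and the evoked PSCs reach
// all targets on the following substep.
// [[Rcpp::export]]
List sim_core_cpp(const NumericMatrix& wt,
                  const LogicalVector& is_exc,
                  const NumericVector& a, const NumericVector& b,
                  const NumericVector& cc, const NumericVector& d,
                  const NumericVector& noise_mu, const NumericVector& noise_sd,
                  const NumericMatrix& ext, const NumericMatrix& gain,
                  const NumericVector& v0, const NumericVector& u0,
                  const double dt, const double tau_e, const double tau_i,
                  const int noise_hold) {
  const int n = v0.size();
  const int nsub = ext.nrow();
  const int k = ext.ncol();
  if (wt.nrow() != n || wt.ncol() != n)
    stop("weight matrix does not match the number of neurons");
  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);
  NumericVector v = clone(v0), u = clone(u0);
  std::vector<double> psc_e(n, 0.0), psc_i(n, 0.0), eps(n, 0.0);
  std::vector<double> sp_time;
  std::vector<int> sp_id, fired;
  sp_time.reserve(4096); sp_id.reserve(4096); fired.reserve(256);

  RNGScope scope;
  for (int t = 0; t < nsub; ++t) {
    fired.clear();
    const bool redraw = (t % noise_hold) == 0;
    for (int j = 0; j < n; ++j) {
      psc_e[j] *= de;
      psc_i[j] *= di;
      if (redraw) eps[j] = R::rnorm(noise_mu[j], noise_sd[j]);
      double I = psc_e[j] + psc_i[j] + eps[j];
      for (int q = 0; q < k; ++q) {
        const double g = gain(j, q);
        if (g != 0.0) I += g * ext(t, q);
      }
      const double vj = v[j], uj = u[j];
      v[j] = vj + dt * (0.04 * vj * vj + 5.0 * vj + 140.0 - uj + I);
      u[j] = uj + dt * a[j] * (b[j] * vj - uj);
      if (v[j] >= 30.0) {
        sp_time.push_back((t + 1) * dt);
        sp_id.push_back(j + 1);
        v[j] = cc[j];
        u[j] += d[j];
        fired.push_back(j);
      } else if (!std::isfinite(v[j]) || !std::isfinite(u[j])) {
        stop("non-finite state for neuron %d at t = %.2f ms", j + 1,
             (t + 1) * dt);
      }
    }
    for (std::size_t s = 0; s < fired.size(); ++s) {
      const int src = fired[s];
      const double* wcol = &wt[0] + static_cast<std::size_t>(n) * src;
      if (is_exc[src]) {
        for (int j = 0; j < n; ++j) psc_e[j] += wcol[j];
      } else {
        for (int j = 0; j < n; ++j) psc_i[j] += wcol[j];
      }
    }
  }
  return List::create(_["time"] = wrap(sp_time), _["neuron"] = wrap(sp_id),
                      _["v"] = v, _["u"] = u);
}
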