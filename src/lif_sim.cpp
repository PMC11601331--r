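#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Conductance-based adaptive leaky integrate-and-fire network of pDp.
// Sources are indexed 0..(n_ob+n_e+n_i-1) in the order OB, E, I; targets
// 0..(n_e+n_i-1) in the order E, I.  Connectivity is passed in compressed
// sparse row form over sources (ptr/tgt/w), so a presynaptic spike walks one
// contiguous slice.  Mitral (OB) spikes are inhomogeneous Poisson with
// piecewise-constant rates; conductances decay exponentially (exact factor
// per step) and jump by the synaptic weight at presynaptic spikes.  E cells
// carry an adaptation current z with tau_ad * dz/dt = a (V - E_rest) - z and
// z <- z + b at each spike.  Uses the R RNG so set.seed() governs everything.

// [[Rcpp::export]]
List lif_simulate(const int n_ob, const int n_e, const int n_i,
                  const IntegerVector& ptr, const IntegerVector& tgt,
                  const NumericVector& w,
                  const List& par,
                  const arma::mat& ob_rates,        // n_ob x n_epochs (Hz)
                  const IntegerVector& epoch_end,   // step index ends (1-based)
                  const double dt,                  // seconds
                  const int n_steps,
                  const int bin_steps,              // steps per rate bin
                  const bool record_spikes = true,
                  const arma::vec& v_init = arma::vec(),  // optional start V
                  const int record_v = -1) {        // 0-based neuron, -1 off
  const int n_t = n_e + n_i;
  auto pd = [&par](const char* nm) { return as<double>(par[nm]); };
  const double C_e = pd("C_e"), C_i = pd("C_i");
  const double gl_e = pd("g_rest_e"), gl_i = pd("g_rest_i");
  const double El_e = pd("E_rest_e"), El_i = pd("E_rest_i");
  const double Ee = pd("E_exc"), Ei = pd("E_inh");
  const double dec_ob = std::exp(-dt / pd("tau_ob"));
  const double dec_ex = std::exp(-dt / pd("tau_exc"));
  const double dec_in = std::exp(-dt / pd("tau_inh"));
  const double a_ad = pd("a"), b_ad = pd("b"), tau_ad = pd("tau_ad");
  const double Vth_e = pd("V_thr_e"), Vth_i = pd("V_thr_i");
  const double Vre_e = pd("V_reset_e"), Vre_i = pd("V_reset_i");
  const int ref_steps = (int)std::round(pd("t_ref") / dt);

  arma::vec V(n_t), g_ob(n_t, arma::fill::zeros),
      g_ex(n_t, arma::fill::zeros), g_in(n_t, arma::fill::zeros),
      z(n_e, arma::fill::zeros);
  arma::ivec refr(n_t, arma::fill::zeros);
  for (int j = 0; j < n_t; ++j) V[j] = (j < n_e) ? El_e : El_i;
  if (v_init.n_elem == (arma::uword)n_t) V = v_init;
  arma::vec vtrace;
  if (record_v >= 0) vtrace.set_size(n_steps);

  const int n_bins = n_steps / bin_steps;
  arma::imat counts(n_t, n_bins, arma::fill::zeros);
  std::vector<double> sp_t;
  std::vector<int> sp_id;              // 0-based over E then I
  std::vector<double> ob_t;
  std::vector<int> ob_id;

  RNGScope scope;
  int epoch = 0;
  for (int s = 0; s < n_steps; ++s) {
    while (epoch < epoch_end.size() - 1 && s >= epoch_end[epoch]) ++epoch;
    const int bin = s / bin_steps;
    // mitral cell Poisson spikes, shared by all their E and I targets
    for (int m = 0; m < n_ob; ++m) {
      double r = ob_rates(m, epoch);
      if (r <= 0.0) continue;
      if (unif_rand() < r * dt) {
        for (int k = ptr[m]; k < ptr[m + 1]; ++k) g_ob[tgt[k]] += w[k];
        if (record_spikes) { ob_t.push_back(s * dt); ob_id.push_back(m); }
      }
    }
    // conductance decay
    g_ob *= dec_ob; g_ex *= dec_ex; g_in *= dec_in;
    if (record_v >= 0) vtrace[s] = V[record_v];
    // membrane + adaptation update, threshold crossing
    for (int j = 0; j < n_t; ++j) {
      const bool isE = j < n_e;
      const double El = isE ? El_e : El_i;
      if (isE) {
        double dz = (a_ad * (V[j] - El_e) - z[j]) * (dt / tau_ad);
        z[j] += dz;
      }
      if (refr[j] > 0) { --refr[j]; V[j] = isE ? Vre_e : Vre_i; continue; }
      const double C = isE ? C_e : C_i, gl = isE ? gl_e : gl_i;
      double I = gl * (El - V[j]) + g_ob[j] * (Ee - V[j]) +
                 g_ex[j] * (Ee - V[j]) + g_in[j] * (Ei - V[j]);
      if (isE) I -= z[j];
      V[j] += dt * I / C;
      if (std::abs(V[j]) > 0.5)
        stop("numerically unstable membrane trajectory at dt = %g s", dt);
      if (V[j] >= (isE ? Vth_e : Vth_i)) {
        V[j] = isE ? Vre_e : Vre_i;
        refr[j] = ref_steps;
        if (isE) z[j] += b_ad;
        counts(j, bin) += 1;
        if (record_spikes) { sp_t.push_back(s * dt); sp_id.push_back(j); }
        const int src = n_ob + j;
        if (isE) {
          for (int k = ptr[src]; k < ptr[src + 1]; ++k) g_ex[tgt[k]] += w[k];
        } else {
          for (int k = ptr[src]; k < ptr[src + 1]; ++k) g_in[tgt[k]] += w[k];
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["spike_t"] = sp_t,
                      _["spike_id"] = sp_id, _["ob_spike_t"] = ob_t,
                      _["ob_spike_id"] = ob_id, _["n_bins"] = n_bins,
                      _["vtrace"] = vtrace);
}
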