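#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Layer codes shared with the R side: 0 = LEC, 1 = GC, 2 = MC, 3 = BC, 4 = HC.
// LEC cells are Poisson sources (rate in lec_rate, Hz); all others are AdEx.
//
// Membrane update is exponential-Euler: exact for the linear conductance
// part, explicit for the AdEx exponential and the adaptation current.
// Table-scale inhibitory conductances (hundreds of nS onto a 6.7 pF granule
// cell) make the voltage equation stiff at dt = 0.1 ms, where a fully
// explicit step diverges; the exponential update is unconditionally stable
// and exact between synaptic events for piecewise-constant conductances.

static const double E_AMPA = 0.0;   // mV
static const double E_GABA = -80.0; // mV
static const double EXP_CAP = 10.0; // cap on AdEx exponent argument
static const double NEVER = -1e18;  // "no spike yet" marker (ms)

// [[Rcpp::export]]
List sim_chunk_cpp(IntegerVector layer,
                   NumericMatrix par,       // n x 9: El gl Cm Vreset Vthr DeltaT alpha tau_w b
                   NumericVector Vm0, NumericVector w0,
                   NumericVector I_inj, NumericVector inh_atten,
                   NumericVector lec_rate,  // Hz, only layer==0 entries used
                   IntegerVector pre, IntegerVector post,  // 1-based neuron ids
                   NumericVector gmax, NumericVector weight0,
                   IntegerVector receptor,  // 0 = AMPA, 1 = GABA
                   LogicalVector plastic,
                   double dt, int n_steps, int step0,
                   int delay_steps, double tau_decay,
                   bool plasticity_on,
                   double eta_plus, double eta_minus,
                   double tau_plus, double tau_minus, double w_max,
                   NumericVector g_exc0, NumericVector g_inh0,
                   NumericMatrix buf_exc0, NumericMatrix buf_inh0, // n x delay_steps
                   NumericVector last_spike0,
                   NumericVector pot_used0, NumericVector dep_used0,
                   bool record_spikes) {
  const int n = layer.size();
  const int m = pre.size();

  NumericVector Vm = clone(Vm0), w = clone(w0);
  NumericVector weight = clone(weight0);
  NumericVector g_exc = clone(g_exc0), g_inh = clone(g_inh0);
  NumericMatrix buf_exc = clone(buf_exc0), buf_inh = clone(buf_inh0);
  NumericVector last_spike = clone(last_spike0);
  // reduced nearest-neighbour bookkeeping: the pre (post) spike time already
  // consumed by a potentiation (depression) pairing on each plastic synapse
  NumericVector pot_used = clone(pot_used0), dep_used = clone(dep_used0);

  // CSR-style adjacency: outgoing synapses per neuron.
  std::vector<int> out_count(n, 0);
  for (int j = 0; j < m; ++j) out_count[pre[j] - 1]++;
  std::vector<int> out_start(n + 1, 0);
  for (int i = 0; i < n; ++i) out_start[i + 1] = out_start[i] + out_count[i];
  std::vector<int> out_idx(m);
  {
    std::vector<int> fill(out_start.begin(), out_start.end() - 1);
    for (int j = 0; j < m; ++j) out_idx[fill[pre[j] - 1]++] = j;
  }
  // Plastic incoming synapses per neuron (perforant-path STDP bookkeeping).
  std::vector<int> pin_count(n, 0);
  for (int j = 0; j < m; ++j) if (plastic[j]) pin_count[post[j] - 1]++;
  std::vector<int> pin_start(n + 1, 0);
  for (int i = 0; i < n; ++i) pin_start[i + 1] = pin_start[i] + pin_count[i];
  std::vector<int> pin_idx(pin_start[n]);
  {
    std::vector<int> fill(pin_start.begin(), pin_start.end() - 1);
    for (int j = 0; j < m; ++j)
      if (plastic[j]) pin_idx[fill[post[j] - 1]++] = j;
  }

  const double decay = std::exp(-dt / tau_decay);
  std::vector<int> spike_id;
  std::vector<double> spike_t;

  std::vector<double> p_spike(n, 0.0);
  for (int i = 0; i < n; ++i)
    if (layer[i] == 0) p_spike[i] = lec_rate[i] * dt * 1e-3;

  for (int s = 0; s < n_steps; ++s) {
    const double t = (step0 + s) * dt;
    const int col = (step0 + s) % delay_steps;

    // Deliver conductance increments scheduled delay_steps ago.
    for (int i = 0; i < n; ++i) {
      g_exc[i] += buf_exc(i, col);
      g_inh[i] += buf_inh(i, col);
      buf_exc(i, col) = 0.0;
      buf_inh(i, col) = 0.0;
    }

    // LEC Poisson sources (presynaptic side of STDP).
    for (int i = 0; i < n; ++i) {
      if (layer[i] != 0 || p_spike[i] <= 0.0) continue;
      if (unif_rand() >= p_spike[i]) continue;
      if (record_spikes) { spike_id.push_back(i + 1); spike_t.push_back(t); }
      for (int k = out_start[i]; k < out_start[i + 1]; ++k) {
        const int j = out_idx[k];
        const int tgt = post[j] - 1;
        const double inc = gmax[j] * weight[j];
        if (receptor[j] == 0) buf_exc(tgt, col) += inc; else buf_inh(tgt, col) += inc;
        if (plasticity_on && plastic[j]) {
          // nearest-neighbour acausal pairing: this pre spike vs the target's
          // most recent post spike (strictly earlier)
          const double lp = last_spike[tgt];
          if (lp > NEVER && t > lp && lp > dep_used[j]) {
            weight[j] -= weight[j] * eta_minus * std::exp(-(t - lp) / tau_minus);
            if (weight[j] < 0.0) weight[j] = 0.0;
            if (weight[j] > w_max) weight[j] = w_max;
            dep_used[j] = lp;
          }
        }
      }
      last_spike[i] = t;
    }

    // AdEx update for DG neurons.
    for (int i = 0; i < n; ++i) {
      if (layer[i] == 0) continue;
      const double El = par(i, 0), gl = par(i, 1), Cm = par(i, 2);
      const double Vreset = par(i, 3), Vthr = par(i, 4), DeltaT = par(i, 5);
      const double alpha = par(i, 6), tau_w = par(i, 7), b = par(i, 8);
      const double ge = g_exc[i];
      const double gi = g_inh[i] * inh_atten[i];
      // units: nS * mV = pA; Cm arrives in nF, so rates use 1000*Cm (pF).
      // Exponential-Euler step: exact for the linear (conductance) part with
      // the AdEx exponential and adaptation treated explicitly. Inside the
      // spike-initiation zone the explicit exponential changes quickly, so
      // the step is refined there (deterministic, state-based).
      const double G = gl + ge + gi;
      const double base = gl * El + ge * E_AMPA + gi * E_GABA + I_inj[i] - w[i];
      const int n_sub =
          (DeltaT > 0.0 && Vm[i] > Vthr - 5.0 * DeltaT) ? 5 : 1;
      const double h = dt / n_sub;
      const double damp = std::exp(-h * G / (1000.0 * Cm));
      double V = Vm[i];
      for (int sub = 0; sub < n_sub; ++sub) {
        double expterm = 0.0;
        if (DeltaT > 0.0) {
          double a = (V - Vthr) / DeltaT;
          if (a > EXP_CAP) a = EXP_CAP;
          expterm = gl * DeltaT * std::exp(a);
        }
        const double Vinf = (base + expterm) / G;
        V = Vinf + (V - Vinf) * damp;
        if (V >= Vthr) break;
      }
      w[i] += dt / tau_w * (alpha * (Vm[i] - El) - w[i]);
      Vm[i] = V;

      if (Vm[i] >= Vthr) {
        Vm[i] = Vreset;
        w[i] += b;
        if (record_spikes) { spike_id.push_back(i + 1); spike_t.push_back(t); }
        for (int k2 = out_start[i]; k2 < out_start[i + 1]; ++k2) {
          const int j = out_idx[k2];
          const int tgt = post[j] - 1;
          const double inc = gmax[j] * weight[j];
          if (receptor[j] == 0) buf_exc(tgt, col) += inc; else buf_inh(tgt, col) += inc;
        }
        if (plasticity_on && layer[i] == 1) {
          // nearest-neighbour causal pairing: each plastic afferent's most
          // recent (strictly earlier) pre spike vs this post spike
          for (int k2 = pin_start[i]; k2 < pin_start[i + 1]; ++k2) {
            const int j = pin_idx[k2];
            const double lp = last_spike[pre[j] - 1];
            if (lp > NEVER && t > lp && lp > pot_used[j]) {
              weight[j] += (w_max - weight[j]) * eta_plus * std::exp(-(t - lp) / tau_plus);
              if (weight[j] < 0.0) weight[j] = 0.0;
              if (weight[j] > w_max) weight[j] = w_max;
              pot_used[j] = lp;
            }
          }
        }
        last_spike[i] = t;
      }
    }

    // End-of-step conductance decay.
    for (int i = 0; i < n; ++i) {
      g_exc[i] *= decay;
      g_inh[i] *= decay;
    }
  }

  return List::create(
      _["spike_id"] = wrap(spike_id), _["spike_t"] = wrap(spike_t),
      _["Vm"] = Vm, _["w"] = w, _["weight"] = weight,
      _["g_exc"] = g_exc, _["g_inh"] = g_inh,
      _["buf_exc"] = buf_exc, _["buf_inh"] = buf_inh,
      _["last_spike"] = last_spike,
      _["pot_used"] = pot_used, _["dep_used"] = dep_used);
}
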