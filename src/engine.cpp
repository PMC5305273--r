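// Clock-driven integrator for the conductance-based LIF network.
//
// Scheme per time step (length dt, which must divide the synaptic delay):
//   1. deliver spikes whose delay expires this step (ring buffer slot);
//   2. apply scheduled conductance kicks;
//   3. advance V by the locally linearised closed form (exponential Euler)
//      holding G fixed over the step; refractory neurons stay clamped at
//      V_rest while their conductances keep decaying;
//   4. decay G_E, G_I and the plasticity traces by their exact factors;
//   5. register threshold crossings at end of step: reset, start refractory
//      clock, enqueue delayed delivery, increment trace, and apply the
//      inhibitory STDP updates at the spike event.
//
// Everything is deterministic: no RNG lives in the engine.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate(int n, int n_exc,
                  IntegerVector row_ptr, IntegerVector col,
                  NumericVector w_in, LogicalVector inh_syn,
                  LogicalVector plastic,
                  NumericVector V_in, NumericVector gE_in,
                  NumericVector gI_in, NumericVector ref_in,
                  NumericVector trace_in,
                  IntegerVector inflight_step, IntegerVector inflight_id,
                  double t0, double duration, double dt, double delay,
                  List np, NumericVector I_extra,
                  double eta, double alpha, double tau_stdp, double g_min,
                  IntegerVector kick_step, IntegerVector kick_id,
                  NumericVector kick_g,
                  IntegerVector record_ids, bool record_g) {
  const double C = np["C"], gl = np["G_leak"], Vrest = np["V_rest"],
               Vth = np["V_th"], VE = np["V_E"], VI = np["V_I"],
               tau_rp = np["tau_rp"], tauE = np["tau_E"], tauI = np["tau_I"],
               I_const = np["I_const"], I_e = np["I_e"], I_i = np["I_i"];

  const int steps = (int)std::lround(duration / dt);
  const int D = (int)std::lround(delay / dt);
  if (std::fabs(D * dt - delay) > 1e-9)
    stop("dt must divide the synaptic delay exactly");
  const int ring_len = D + 1;

  const double fE = std::exp(-dt / tauE);
  const double fI = std::exp(-dt / tauI);
  const double fx = std::exp(-dt / tau_stdp);
  const bool learn = eta > 0.0;

  NumericVector w = clone(w_in);
  std::vector<double> V(V_in.begin(), V_in.end());
  std::vector<double> gE(gE_in.begin(), gE_in.end());
  std::vector<double> gI(gI_in.begin(), gI_in.end());
  std::vector<double> ref(ref_in.begin(), ref_in.end());
  std::vector<double> x(trace_in.begin(), trace_in.end());

  // presynaptic id of each synapse (needed for the postsynaptic STDP update)
  std::vector<int> syn_pre;
  // incoming plastic synapse indices per excitatory neuron
  std::vector<int> inc_ptr, inc_syn;
  if (learn) {
    const int nsyn = col.size();
    syn_pre.assign(nsyn, 0);
    for (int j = 0; j < n; ++j)
      for (int s = row_ptr[j]; s < row_ptr[j + 1]; ++s) syn_pre[s] = j;
    std::vector<int> cnt(n_exc, 0);
    for (int s = 0; s < nsyn; ++s)
      if (plastic[s]) ++cnt[col[s]];
    inc_ptr.assign(n_exc + 1, 0);
    for (int i = 0; i < n_exc; ++i) inc_ptr[i + 1] = inc_ptr[i] + cnt[i];
    inc_syn.assign(inc_ptr[n_exc], 0);
    std::vector<int> fill(inc_ptr.begin(), inc_ptr.end() - 1);
    for (int s = 0; s < nsyn; ++s)
      if (plastic[s]) inc_syn[fill[col[s]]++] = s;
  }

  std::vector<std::vector<int>> ring(ring_len);
  for (int e = 0; e < inflight_step.size(); ++e) {
    int s = inflight_step[e];
    if (s < 0 || s > D) stop("in-flight spike outside the delay horizon");
    ring[s % ring_len].push_back(inflight_id[e]);
  }

  std::vector<double> sp_t;
  std::vector<int> sp_i;
  sp_t.reserve(1024);
  sp_i.reserve(1024);

  const int n_rec = record_ids.size();
  NumericMatrix recV(n_rec > 0 ? steps : 0, n_rec);
  NumericMatrix recGE(record_g && n_rec ? steps : 0,
                      record_g ? n_rec : 0);
  NumericMatrix recGI(record_g && n_rec ? steps : 0,
                      record_g ? n_rec : 0);

  int kp = 0;
  const int n_kick = kick_step.size();

  for (int s = 0; s < steps; ++s) {
    // 1. deliveries
    std::vector<int> &slot = ring[s % ring_len];
    for (size_t q = 0; q < slot.size(); ++q) {
      const int j = slot[q];
      for (int e = row_ptr[j]; e < row_ptr[j + 1]; ++e) {
        if (inh_syn[e]) gI[col[e]] += w[e];
        else            gE[col[e]] += w[e];
      }
    }
    slot.clear();

    // 2. kicks scheduled for this step
    while (kp < n_kick && kick_step[kp] == s) {
      gE[kick_id[kp]] += kick_g[kp];
      ++kp;
    }

    // 3-5. integrate, decay, threshold.  Traces decay for everyone first so
    // that STDP reads during this step's spikes see a uniform decay state.
    for (int i = 0; i < n; ++i) x[i] *= fx;
    for (int i = 0; i < n; ++i) {
      const double ge = gE[i], gi = gI[i];
      bool can_fire = false;
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        V[i] = Vrest;
      } else {
        const double gtot = gl + ge + gi;
        const double I = I_const + ((i < n_exc) ? I_e : I_i) + I_extra[i];
        const double vinf = (gl * Vrest + ge * VE + gi * VI + I) / gtot;
        V[i] = vinf + (V[i] - vinf) * std::exp(-dt * gtot / C);
        can_fire = true;
      }
      gE[i] = ge * fE;
      gI[i] = gi * fI;

      if (can_fire && V[i] >= Vth) {
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential at neuron %d", i + 1);
        sp_t.push_back(t0 + (s + 1) * dt);
        sp_i.push_back(i);
        V[i] = Vrest;
        ref[i] = tau_rp;
        x[i] += 1.0;
        ring[(s + 1 + D) % ring_len].push_back(i);
        if (learn) {
          if (i >= n_exc) {
            // presynaptic (inhibitory) spike on its plastic outputs
            for (int e = row_ptr[i]; e < row_ptr[i + 1]; ++e) {
              if (plastic[e]) {
                w[e] += eta * (x[col[e]] - alpha);
                if (w[e] < g_min) w[e] = g_min;
              }
            }
          } else {
            // postsynaptic (excitatory) spike on its plastic inputs
            for (int q = inc_ptr[i]; q < inc_ptr[i + 1]; ++q) {
              const int e = inc_syn[q];
              w[e] += eta * x[syn_pre[e]];
              if (w[e] < g_min) w[e] = g_min;
            }
          }
        }
      }
    }

    if (n_rec) {
      for (int r = 0; r < n_rec; ++r) {
        const int i = record_ids[r];
        recV(s, r) = V[i];
        if (record_g) {
          recGE(s, r) = gE[i];
          recGI(s, r) = gI[i];
        }
      }
    }

    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // serialise in-flight spikes as steps-until-delivery relative to the next
  // step after this call
  std::vector<int> out_step, out_id;
  for (int off = 0; off < ring_len; ++off) {
    const int slot_idx = (steps + off) % ring_len;
    for (size_t q = 0; q < ring[slot_idx].size(); ++q) {
      out_step.push_back(off);
      out_id.push_back(ring[slot_idx][q]);
    }
  }

  return List::create(
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_i"] = IntegerVector(sp_i.begin(), sp_i.end()),
      _["V"] = NumericVector(V.begin(), V.end()),
      _["gE"] = NumericVector(gE.begin(), gE.end()),
      _["gI"] = NumericVector(gI.begin(), gI.end()),
      _["ref"] = NumericVector(ref.begin(), ref.end()),
      _["trace"] = NumericVector(x.begin(), x.end()),
      _["w"] = w,
      _["inflight_step"] = IntegerVector(out_step.begin(), out_step.end()),
      _["inflight_id"] = IntegerVector(out_id.begin(), out_id.end()),
      _["recV"] = recV, _["recGE"] = recGE, _["recGI"] = recGI);
}

// Brute-force stochastic oracle for the diffusion approximation: a single
// current-based LIF neuron driven by white noise with prescribed stationary
// mean mu and fluctuation scale sigma (Brunel convention: free membrane
// variance sigma^2/2, i.e. dV = ((mu-V)/tau)dt + (sigma/sqrt(tau))dW).
// Euler-Maruyama with reset and refractoriness;
// independent of the network engine above.
// [[Rcpp::export]]
double cpp_noisy_lif_rate(double mu, double sigma, double tau_m,
                          double V_rest, double V_th, double tau_rp,
                          double duration, double dt, int seed) {
  // xorshift64* generator + Box-Muller, self-contained for reproducibility
  uint64_t state = (uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL;
  auto next_u = [&]() {
    state ^= state >> 12;
    state ^= state << 25;
    state ^= state >> 27;
    return (double)((state * 2685821657736338717ULL) >> 11) /
           9007199254740992.0;
  };
  bool have_spare = false;
  double spare = 0.0;
  auto next_norm = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = next_u(), u2 = next_u();
    while (u1 <= 1e-300) u1 = next_u();
    const double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  };

  const long steps = (long)std::lround(duration / dt);
  const double drift = dt / tau_m;
  const double noise = sigma * std::sqrt(dt / tau_m);
  double V = V_rest, ref = 0.0;
  long nsp = 0;
  for (long s = 0; s < steps; ++s) {
    if (ref > 0.0) {
      ref -= dt;
      V = V_rest;
      continue;
    }
    V += (mu - V) * drift + noise * next_norm();
    if (V >= V_th) {
      ++nsp;
      V = V_rest;
      ref = tau_rp;
    }
  }
  return (double)nsp / (duration / 1000.0); // spikes/s, duration in ms
}
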