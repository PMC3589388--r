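// Event-driven simulation of rule-based leaky integrate-and-fire neurons.
//
// Each neuron carries per-channel synaptic contributions with closed-form
// exponential decay between events, a decaying post-spike threshold
// elevation and hyperpolarization, absolute refractoriness and
// depolarization blockade.  Synaptic deliveries, forced stimulus inputs
// (touch / microstimulation) and per-neuron Poisson background drive are
// processed through a single global priority queue with deterministic
// tie-breaking; spike-triggered microstimulation pulses are generated
// online (closed loop) from the reference neuron's spikes.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <functional>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Event {
  double t;
  int type;   // 0 touch, 1 microstim pulse, 2 background, 3 delivery
  int idx;    // neuron (types 0-2 unused/neuron) or synapse index (type 3)
  int64_t seq;
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.type != b.type) return a.type > b.type;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.seq > b.seq;
  }
};

// deterministic uniform/exponential from a fixed-width generator, so that
// identical seeds give identical event streams on every platform
inline double unif01(std::mt19937_64& rng) {
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
inline double rexp1(std::mt19937_64& rng, double rate) {
  return -std::log(unif01(rng)) / rate;
}

}  // namespace

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(
    IntegerVector pop_idx,        // 0-based population index per neuron
    NumericMatrix pop_tau,        // n_pop x 3 receptor time constants (ms)
    NumericMatrix pop_E,          // n_pop x 3 reversal potentials (mV)
    NumericVector pop_vth, NumericVector pop_vblock,
    NumericVector pop_refrac, NumericVector pop_R, NumericVector pop_tauR,
    NumericVector pop_H, NumericVector pop_tauH,
    IntegerVector syn_pre, IntegerVector syn_post, IntegerVector syn_channel,
    NumericVector syn_weight, NumericVector syn_wbase, NumericVector syn_delay,
    LogicalVector syn_plastic,
    double stdp_eps_frac, double stdp_window, double wmax_factor,
    double bg_rate_hz, double bg_weight,
    double bg_shared_rate_hz, double bg_shared_weight,
    NumericVector touch_times, IntegerVector touch_targets, double touch_weight,
    double touch_spread_ms, double touch_jitter_ms,
    NumericVector pulse_times, IntegerVector pulse_targets, double pulse_weight,
    NumericVector ext_times, IntegerVector ext_targets, NumericVector ext_weights,
    double pulse_doublet_ms,
    int reference_id, double cond_start, double cond_end,
    double stdp_t0, double stdp_t1,
    double trigger_delay, double lockout,
    double duration, double seed, double max_spikes) {

  const int n = pop_idx.size();
  const int n_syn = syn_pre.size();
  const double NEG_INF = -1e300;

  // neuron state
  std::vector<double> g0(n, 0.0), g1(n, 0.0), g2(n, 0.0);
  std::vector<double> hyper(n, 0.0), thr_off(n, 0.0);
  std::vector<double> t_upd(n, 0.0), last_spike(n, NEG_INF);

  // synapse state
  std::vector<double> w(syn_weight.begin(), syn_weight.end());
  std::vector<double> eps(n_syn), wmax(n_syn), last_arr(n_syn, NEG_INF);
  for (int s = 0; s < n_syn; ++s) {
    eps[s] = stdp_eps_frac * syn_wbase[s];
    wmax[s] = wmax_factor * syn_wbase[s];
  }

  // CSR efferent lists and afferent-plastic lists
  std::vector<int> eff_cnt(n + 1, 0), aff_cnt(n + 1, 0);
  for (int s = 0; s < n_syn; ++s) {
    eff_cnt[syn_pre[s] + 1]++;
    if (syn_plastic[s]) aff_cnt[syn_post[s] + 1]++;
  }
  for (int i = 0; i < n; ++i) {
    eff_cnt[i + 1] += eff_cnt[i];
    aff_cnt[i + 1] += aff_cnt[i];
  }
  std::vector<int> eff(n_syn), aff(aff_cnt[n]);
  {
    std::vector<int> ep(eff_cnt.begin(), eff_cnt.end() - 1),
                     ap(aff_cnt.begin(), aff_cnt.end() - 1);
    for (int s = 0; s < n_syn; ++s) {
      eff[ep[syn_pre[s]]++] = s;
      if (syn_plastic[s]) aff[ap[syn_post[s]]++] = s;
    }
  }

  std::priority_queue<Event, std::vector<Event>, EventCmp> q;
  int64_t seq = 0;

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  if (bg_rate_hz > 0) {
    const double rate_ms = bg_rate_hz / 1000.0;
    for (int i = 0; i < n; ++i)
      q.push({rexp1(rng, rate_ms), 2, i, seq++});
  }
  if (bg_shared_rate_hz > 0)
    q.push({rexp1(rng, bg_shared_rate_hz / 1000.0), 6, -1, seq++});
  // fixed per-target touch latency offsets (receptor/transduction spread)
  std::vector<double> touch_off(touch_targets.size(), 0.0);
  for (int k = 0; k < touch_targets.size(); ++k)
    touch_off[k] = touch_spread_ms > 0 ? unif01(rng) * touch_spread_ms : 0.0;
  for (int k = 0; k < touch_times.size(); ++k)
    q.push({touch_times[k], 0, -1, seq++});
  for (int k = 0; k < pulse_times.size(); ++k)
    q.push({pulse_times[k], 1, -1, seq++});
  for (int k = 0; k < ext_times.size(); ++k)
    q.push({ext_times[k], 0, n + k, seq++});   // generic per-event input

  std::vector<int> out_id;
  std::vector<double> out_t, out_pulse;
  out_id.reserve(1 << 16);
  out_t.reserve(1 << 16);
  for (int k = 0; k < pulse_times.size(); ++k) out_pulse.push_back(pulse_times[k]);
  double last_pulse = NEG_INF;
  const double bg_rate_ms = bg_rate_hz / 1000.0;

  // forward declaration workaround via lambdas
  std::function<void(int, double)> fire_check;

  auto decay = [&](int i, double t) {
    const double dt = t - t_upd[i];
    if (dt <= 0) return;
    const int p = pop_idx[i];
    g0[i] *= std::exp(-dt / pop_tau(p, 0));
    g1[i] *= std::exp(-dt / pop_tau(p, 1));
    g2[i] *= std::exp(-dt / pop_tau(p, 2));
    hyper[i] *= std::exp(-dt / pop_tauH[p]);
    thr_off[i] *= std::exp(-dt / pop_tauR[p]);
    t_upd[i] = t;
  };

  long n_events = 0;

  fire_check = [&](int i, double t) {
    const int p = pop_idx[i];
    const double V = g0[i] + g1[i] + g2[i] + hyper[i];
    if (V < pop_vth[p] + thr_off[i]) return;
    if (V >= pop_vblock[p]) return;           // depolarization blockade
    if (t - last_spike[i] <= pop_refrac[p]) return;
    // --- spike ---
    out_id.push_back(i);
    out_t.push_back(t);
    if ((double)out_id.size() > max_spikes)
      stop("spike count exceeded max_spikes: runaway network activity");
    // STDP potentiation: causal inputs within the learning window
    if (t >= stdp_t0 && t < stdp_t1) {
      for (int k = aff_cnt[i]; k < aff_cnt[i + 1]; ++k) {
        const int s = aff[k];
        const double dt = t - last_arr[s];
        // causal-inclusive: the input that triggers the spike (dt == 0 in
        // event time) stems from a presynaptic spike one delay earlier
        if (dt >= 0 && dt <= stdp_window)
          w[s] = std::min(w[s] + eps[s], wmax[s]);
      }
    }
    last_spike[i] = t;
    thr_off[i] += pop_R[p];
    hyper[i] -= pop_H[p];
    g0[i] = g1[i] = g2[i] = 0.0;              // membrane resets after spike
    for (int k = eff_cnt[i]; k < eff_cnt[i + 1]; ++k) {
      const int s = eff[k];
      const double ta = t + syn_delay[s];
      if (ta <= duration) q.push({ta, 3, s, seq++});
    }
    // closed-loop spike-triggered microstimulation
    if (i == reference_id && t >= cond_start && t < cond_end) {
      const double tp = t + trigger_delay;
      if (tp - last_pulse >= lockout && tp <= duration && tp < cond_end) {
        q.push({tp, 1, -1, seq++});
        out_pulse.push_back(tp);
        last_pulse = tp;
      }
    }
  };

  // inputs arriving during the absolute refractory period are shunted:
  // they contribute nothing to the membrane (rule-based IF convention)
  auto forced_input = [&](int i, double t, double wgt) {
    if (t - last_spike[i] <= pop_refrac[pop_idx[i]]) return;
    decay(i, t);
    const int p = pop_idx[i];
    g0[i] += wgt * pop_E(p, 0);               // AMPA-like depolarizing input
    fire_check(i, t);
  };

  while (!q.empty()) {
    Event ev = q.top();
    q.pop();
    if (ev.t > duration) break;
    if (++n_events % 1048576 == 0) Rcpp::checkUserInterrupt();
    switch (ev.type) {
      case 0:  // touch set, or a generic single-neuron external input
        if (ev.idx >= n) {
          const int k = ev.idx - n;
          forced_input(ext_targets[k], ev.t, ext_weights[k]);
        } else {
          // relay cells respond with fixed offsets plus trial jitter
          for (int k = 0; k < touch_targets.size(); ++k) {
            double jit = touch_jitter_ms > 0 ? rexp1(rng, 1.0 / touch_jitter_ms) : 0.0;
            const double ta = ev.t + touch_off[k] + jit;
            if (ta <= duration) q.push({ta, 7, touch_targets[k], seq++});
          }
        }
        break;
      case 7:  // jittered touch delivery to one relay cell
        forced_input(ev.idx, ev.t, touch_weight);
        break;
      case 1:  // microstimulation pulse (first phase of the doublet)
        if (pulse_doublet_ms > 0 && ev.t + pulse_doublet_ms <= duration)
          q.push({ev.t + pulse_doublet_ms, 5, -1, seq++});
        // fall through to delivery
      case 5:  // doublet partner
        for (int k = 0; k < pulse_targets.size(); ++k)
          forced_input(pulse_targets[k], ev.t, pulse_weight);
        break;
      case 2: {  // per-neuron Poisson background drive
        forced_input(ev.idx, ev.t, bg_weight);
        const double tn = ev.t + rexp1(rng, bg_rate_ms);
        if (tn <= duration) q.push({tn, 2, ev.idx, seq++});
        break;
      }
      case 6: {  // shared slow fluctuation: common NMDA-channel input,
                 // modulating all cells coherently over ~100 ms
        for (int i = 0; i < n; ++i) {
          decay(i, ev.t);
          g1[i] += bg_shared_weight * pop_E(pop_idx[i], 1);
          fire_check(i, ev.t);
        }
        const double tn = ev.t + rexp1(rng, bg_shared_rate_hz / 1000.0);
        if (tn <= duration) q.push({tn, 6, -1, seq++});
        break;
      }
      case 3: {  // synaptic delivery
        const int s = ev.idx;
        const int i = syn_post[s];
        // STDP depression: input arriving just after the postsynaptic spike
        if (syn_plastic[s]) {
          const double dt = ev.t - last_spike[i];
          if (dt > 0 && dt <= stdp_window && ev.t >= stdp_t0 && ev.t < stdp_t1)
            w[s] = std::max(w[s] - eps[s], 0.0);
          last_arr[s] = ev.t;
        }
        if (ev.t - last_spike[i] <= pop_refrac[pop_idx[i]]) break;  // shunted
        decay(i, ev.t);
        const int p = pop_idx[i];
        const int c = syn_channel[s];
        if (c == 0) g0[i] += w[s] * pop_E(p, 0);
        else if (c == 1) g1[i] += w[s] * pop_E(p, 1);
        else g2[i] += w[s] * pop_E(p, 2);
        fire_check(i, ev.t);
        break;
      }
    }
  }

  std::sort(out_pulse.begin(), out_pulse.end());
  return List::create(
      _["spike_id"] = wrap(out_id),
      _["spike_t_ms"] = wrap(out_t),
      _["pulse_t_ms"] = wrap(out_pulse),
      _["final_weights"] = wrap(w));
}
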