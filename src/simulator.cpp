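// Conductance-based LIF network integrator.
//
// Membrane dynamics per neuron:
//   dV/dt = -(V - E_l)/tau_m - sum_c G_c(t) (V - E_c) / C_m
// where G_c(t) = sum_j g_j s_j(t) aggregates all afferents of channel c
// (c = presynaptic class 0..3, or 4 = external AMPA drive). All synapses
// within a channel share the decay constant tau_syn(c, post_class), so
// the weighted gate sum G_c itself decays exponentially and is
// incremented by the synaptic conductance g_j on each presynaptic
// arrival (delta input integrating to unity per event).
//
// Integration: classical RK4 on V with the conductances decaying
// analytically within the step (exact exponential evaluated at the
// half- and full-step substage times); arrivals are applied at step
// boundaries. Spike: V >= V_thr at the end of a step -> spike recorded
// at (step+1)*dt, V reset and clamped for the refractory period.
// Spikes propagate to targets after a per-edge delay rounded to the dt
// grid (minimum one step).
//
// All randomness (background and feedforward Poisson trains) is drawn
// from R's RNG, so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double exp_interval_ms(double rate_hz) {
  // next inter-arrival time in ms for a Poisson process at rate_hz
  return R::exp_rand() * 1000.0 / rate_hz;
}

// [[Rcpp::export]]
List simulate_trial_cpp(int n_neurons,
                        IntegerVector class_of,        // 1..4
                        IntegerVector edge_ptr,        // CSR by presyn neuron, 0-based
                        IntegerVector edge_target,     // 0-based
                        NumericVector edge_weight,     // nS
                        IntegerVector edge_delay,      // steps, >= 1
                        int n_fibers,
                        IntegerVector ff_ptr,          // CSR by fiber, 0-based
                        IntegerVector ff_target,
                        NumericVector ff_weight,
                        IntegerVector ff_delay,
                        NumericVector tau_m,           // per class, ms
                        IntegerVector tau_ref_steps,   // per class
                        double C_m, double E_l, double V_thr, double V_reset,
                        NumericMatrix tau_syn,         // 5 x 4 (channel x post class)
                        NumericVector E_rev,           // length 5, mV
                        NumericVector bg_rate,         // per neuron, Hz
                        double bg_g,
                        double ff_rate,                // Hz per fiber
                        double onset_ms,
                        double dt, int n_steps,
                        double const_g_ext,
                        int record_v)                  // 0-based neuron id or -1
{
  const int NCH = 5;
  if (class_of.size() != n_neurons) stop("class_of length mismatch");

  // decay factors per (channel, class)
  std::vector<double> dec_full(NCH * 4), dec_half(NCH * 4);
  for (int c = 0; c < NCH; ++c)
    for (int k = 0; k < 4; ++k) {
      double tau = tau_syn(c, k);
      dec_full[c * 4 + k] = std::exp(-dt / tau);
      dec_half[c * 4 + k] = std::exp(-0.5 * dt / tau);
    }

  // delay ring buffer
  int max_delay = 1;
  for (int e = 0; e < edge_delay.size(); ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
  for (int e = 0; e < ff_delay.size(); ++e)
    if (ff_delay[e] > max_delay) max_delay = ff_delay[e];
  const int L = max_delay + 2;
  const size_t plane = (size_t)NCH * n_neurons;
  std::vector<double> pending((size_t)L * plane, 0.0);

  std::vector<double> G(plane, 0.0);
  std::vector<double> V(n_neurons, E_l);
  std::vector<int> refr(n_neurons, 0);

  // per-neuron background arrival clocks
  std::vector<double> next_bg(n_neurons);
  for (int i = 0; i < n_neurons; ++i)
    next_bg[i] = bg_rate[i] > 0 ? exp_interval_ms(bg_rate[i]) : R_PosInf;

  // feedforward fiber clocks (silent before onset)
  std::vector<double> next_ff(n_fibers);
  for (int f = 0; f < n_fibers; ++f)
    next_ff[f] = ff_rate > 0 ? onset_ms + exp_interval_ms(ff_rate) : R_PosInf;

  std::vector<int> spike_id;
  std::vector<double> spike_time;
  spike_id.reserve(1024);
  spike_time.reserve(1024);
  std::vector<int> fired;
  fired.reserve(256);

  NumericVector vtrace(record_v >= 0 ? n_steps : 0);

  const double inv_Cm = 1.0 / C_m;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int slot = step % L;
    double* pend_now = &pending[(size_t)slot * plane];

    // arrivals scheduled for this boundary
    for (size_t idx = 0; idx < plane; ++idx) {
      G[idx] += pend_now[idx];
      pend_now[idx] = 0.0;
    }

    // background Poisson arrivals in [t, t+dt) -> external channel now
    {
      double* Gx = &G[(size_t)4 * n_neurons];
      const double t_end = t + dt;
      for (int i = 0; i < n_neurons; ++i) {
        while (next_bg[i] < t_end) {
          Gx[i] += bg_g;
          next_bg[i] += exp_interval_ms(bg_rate[i]);
        }
      }
    }

    // feedforward fiber spikes -> delayed delivery to targets
    {
      const double t_end = t + dt;
      for (int f = 0; f < n_fibers; ++f) {
        while (next_ff[f] < t_end) {
          for (int e = ff_ptr[f]; e < ff_ptr[f + 1]; ++e) {
            int arr = (step + ff_delay[e]) % L;
            pending[(size_t)arr * plane + (size_t)4 * n_neurons + ff_target[e]]
              += ff_weight[e];
          }
          next_ff[f] += exp_interval_ms(ff_rate);
        }
      }
    }

    // integrate membrane potentials
    fired.clear();
    for (int i = 0; i < n_neurons; ++i) {
      const int k = class_of[i] - 1;
      if (refr[i] > 0) {
        --refr[i];
        V[i] = V_reset;
        if (record_v == i) vtrace[step] = V[i];
        continue;
      }
      // channel sums at stage times 0, dt/2, dt
      double P0 = const_g_ext, Ph = const_g_ext, P1 = const_g_ext;
      double Q0 = 0.0, Qh = 0.0, Q1 = 0.0;
      for (int c = 0; c < NCH; ++c) {
        const double g = G[(size_t)c * n_neurons + i];
        if (g == 0.0) continue;
        const double dh = dec_half[c * 4 + k];
        const double df = dec_full[c * 4 + k];
        const double e = E_rev[c];
        P0 += g;        Q0 += g * e;
        Ph += g * dh;   Qh += g * dh * e;
        P1 += g * df;   Q1 += g * df * e;
      }
      const double inv_tm = 1.0 / tau_m[k];
      const double A0 = E_l * inv_tm + Q0 * inv_Cm, B0 = inv_tm + P0 * inv_Cm;
      const double Ah = E_l * inv_tm + Qh * inv_Cm, Bh = inv_tm + Ph * inv_Cm;
      const double A1 = E_l * inv_tm + Q1 * inv_Cm, B1 = inv_tm + P1 * inv_Cm;

      double v = V[i];
      const double k1 = A0 - B0 * v;
      const double k2 = Ah - Bh * (v + 0.5 * dt * k1);
      const double k3 = Ah - Bh * (v + 0.5 * dt * k2);
      const double k4 = A1 - B1 * (v + dt * k3);
      v += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

      if (!std::isfinite(v))
        stop("membrane potential diverged at t = %g ms (neuron %d)", t, i + 1);
      V[i] = v;
      if (record_v == i) vtrace[step] = v;
      if (v >= V_thr) fired.push_back(i);
    }

    // spikes: record, reset, clamp, propagate
    for (size_t s = 0; s < fired.size(); ++s) {
      const int i = fired[s];
      const int k = class_of[i] - 1;
      spike_id.push_back(i + 1);
      spike_time.push_back((step + 1) * dt);
      V[i] = V_reset;
      refr[i] = tau_ref_steps[k];
      const int ch_base = k * n_neurons;
      for (int e = edge_ptr[i]; e < edge_ptr[i + 1]; ++e) {
        const int arr = (step + 1 + edge_delay[e]) % L;
        pending[(size_t)arr * plane + ch_base + edge_target[e]] += edge_weight[e];
      }
    }

    // gates decay to the next boundary
    for (int c = 0; c < NCH; ++c) {
      double* Gc = &G[(size_t)c * n_neurons];
      const double* dc = &dec_full[c * 4];
      for (int i = 0; i < n_neurons; ++i) Gc[i] *= dc[class_of[i] - 1];
    }

    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["neuron_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["time"] = NumericVector(spike_time.begin(), spike_time.end()),
    _["v_final"] = NumericVector(V.begin(), V.end()));
  if (record_v >= 0) out["v_trace"] = vtrace;
  return out;
}
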