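#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley gating kinetics of the adapting cortical neuron model.
// Na+ activation is instantaneous (m = m_inf); h and n relax with
// voltage-dependent time constants; the M-current gate z relaxes with a
// fixed time constant tau_z.
static inline double m_inf(double V)  { return 1.0 / (1.0 + exp((-V - 30.0) / 9.5)); }
static inline double n_inf(double V)  { return 1.0 / (1.0 + exp((-V - 30.0) / 10.0)); }
static inline double z_inf(double V)  { return 1.0 / (1.0 + exp((-V - 39.0) / 5.0)); }
static inline double tau_n(double V)  { return 0.37 + 1.85 / (1.0 + exp((V + 27.0) / 15.0)); }

struct Deriv { double dV, dh, dn, dz; };

// params layout: C, gNa, gKdr, gL, VNa, VK, VL, tau_z
static inline Deriv hh_deriv(double V, double h, double n, double z,
                             double gKs, double Iext,
                             double ge, double gi, double Ee, double Ei,
                             const double *p) {
  double e1 = exp((V + 40.5) / 6.0);   // shared by h_inf and tau_h
  double hinf = 1.0 / (1.0 + e1);
  double tauh = 0.37 + 2.78 * hinf;
  double m = m_inf(V);
  double INa  = p[1] * m * m * m * h * (V - p[4]);
  double IKdr = p[2] * n * n * n * n * (V - p[5]);
  double IKs  = gKs * z * (V - p[5]);
  double IL   = p[3] * (V - p[6]);
  double Isyn = ge * (V - Ee) + gi * (V - Ei);
  Deriv d;
  d.dV = (-INa - IKdr - IKs - IL + Iext - Isyn) / p[0];
  d.dh = (hinf - h) / tauh;
  d.dn = (n_inf(V) - n) / tau_n(V);
  d.dz = (z_inf(V) - z) / p[7];
  return d;
}

// Fixed-step RK4 network integrator with exponential-decay conductance
// synapses. Two conductance accumulators per cell (excitatory, inhibitory)
// are held constant within a step, decayed by exp(-dt/tau) at the end of
// the step, and incremented by the synaptic weight when a presynaptic
// spike is detected, which reproduces the per-spike kernel sum
// w * exp(-(t - t_k)/tau) exactly at the step boundaries.
//
// Edges in CSR by source: targets of source j are edge_tgt[edge_ptr[j] ..
// edge_ptr[j+1]-1] (0-based) with weights edge_w; is_exc flags excitatory
// sources. Spike detection: upward crossing of 0 mV with a lockout
// (detection only, not dynamics). Gate initial values are set to their
// steady state at the initial voltage.
// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(int n_cells,
                     IntegerVector is_exc,
                     NumericVector gks,
                     IntegerVector edge_ptr,
                     IntegerVector edge_tgt,
                     NumericVector edge_w,
                     NumericVector idrive,
                     bool noise_on, double noise_rate, double noise_amp,
                     double noise_width,
                     double tau_e, double tau_i, double e_exc, double e_inh,
                     NumericVector params,
                     double dt, double duration, double lockout_ms,
                     NumericVector v0,
                     IntegerVector record_ids,   // 0-based cell indices
                     double record_every,        // ms; <= 0 disables
                     bool record_syn) {
  const double *p = REAL(params);
  std::vector<double> V(n_cells), Vprev(n_cells), h(n_cells), n_(n_cells), z(n_cells);
  std::vector<double> ge(n_cells, 0.0), gi(n_cells, 0.0), Inoise(n_cells, 0.0);
  for (int i = 0; i < n_cells; ++i) {
    V[i] = v0[i];
    h[i] = 1.0 / (1.0 + exp((V[i] + 40.5) / 6.0));
    n_[i] = n_inf(V[i]);
    z[i] = z_inf(V[i]);
  }

  long n_steps = (long)std::floor(duration / dt + 0.5);
  int lockout_steps = (int)std::ceil(lockout_ms / dt);
  double dec_e = exp(-dt / tau_e), dec_i = exp(-dt / tau_i);

  std::vector<long> last_spike(n_cells, -lockout_steps - 1);
  std::vector<double> spike_t; spike_t.reserve(1 << 16);
  std::vector<int> spike_id;  spike_id.reserve(1 << 16);

  // Poisson current-pulse noise: per-cell next event time; active pulses
  // expire through a FIFO of (end_step, cell); overlapping pulses sum.
  std::vector<double> next_event(n_cells, R_PosInf);
  std::deque<std::pair<long, int> > pulse_ends;
  long width_steps = (long)std::floor(noise_width / dt + 0.5);
  if (noise_on && noise_rate > 0)
    for (int i = 0; i < n_cells; ++i)
      next_event[i] = R::rexp(1.0 / noise_rate);

  int n_rec = record_ids.size();
  long rec_stride = record_every > 0 ? (long)std::floor(record_every / dt + 0.5) : 0;
  long n_rec_t = (rec_stride > 0 && n_rec > 0) ? (n_steps / rec_stride + 1) : 0;
  NumericMatrix vrec(n_rec_t, n_rec);
  NumericMatrix gerec(record_syn ? n_rec_t : 0, record_syn ? n_rec : 0);
  NumericMatrix girec(record_syn ? n_rec_t : 0, record_syn ? n_rec : 0);
  NumericVector rec_times(n_rec_t);
  long rec_row = 0;

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;

    if (n_rec_t > 0 && step % rec_stride == 0 && rec_row < n_rec_t) {
      rec_times[rec_row] = t;
      for (int k = 0; k < n_rec; ++k) {
        int id = record_ids[k];
        vrec(rec_row, k) = V[id];
        if (record_syn) { gerec(rec_row, k) = ge[id]; girec(rec_row, k) = gi[id]; }
      }
      ++rec_row;
    }
    if (step == n_steps) break;

    if (noise_on && noise_rate > 0) {
      while (!pulse_ends.empty() && pulse_ends.front().first <= step) {
        Inoise[pulse_ends.front().second] -= noise_amp;
        pulse_ends.pop_front();
      }
      for (int i = 0; i < n_cells; ++i) {
        while (next_event[i] <= t) {
          Inoise[i] += noise_amp;
          pulse_ends.push_back(std::make_pair(step + width_steps, i));
          next_event[i] += R::rexp(1.0 / noise_rate);
        }
      }
    }

    for (int i = 0; i < n_cells; ++i) {
      double Iext = idrive[i] + Inoise[i];
      double Vi = V[i], hi = h[i], ni = n_[i], zi = z[i];
      Deriv k1 = hh_deriv(Vi, hi, ni, zi, gks[i], Iext, ge[i], gi[i], e_exc, e_inh, p);
      Deriv k2 = hh_deriv(Vi + 0.5 * dt * k1.dV, hi + 0.5 * dt * k1.dh,
                          ni + 0.5 * dt * k1.dn, zi + 0.5 * dt * k1.dz,
                          gks[i], Iext, ge[i], gi[i], e_exc, e_inh, p);
      Deriv k3 = hh_deriv(Vi + 0.5 * dt * k2.dV, hi + 0.5 * dt * k2.dh,
                          ni + 0.5 * dt * k2.dn, zi + 0.5 * dt * k2.dz,
                          gks[i], Iext, ge[i], gi[i], e_exc, e_inh, p);
      Deriv k4 = hh_deriv(Vi + dt * k3.dV, hi + dt * k3.dh,
                          ni + dt * k3.dn, zi + dt * k3.dz,
                          gks[i], Iext, ge[i], gi[i], e_exc, e_inh, p);
      double Vn = Vi + dt / 6.0 * (k1.dV + 2 * k2.dV + 2 * k3.dV + k4.dV);
      h[i]  = hi + dt / 6.0 * (k1.dh + 2 * k2.dh + 2 * k3.dh + k4.dh);
      n_[i] = ni + dt / 6.0 * (k1.dn + 2 * k2.dn + 2 * k3.dn + k4.dn);
      z[i]  = zi + dt / 6.0 * (k1.dz + 2 * k2.dz + 2 * k3.dz + k4.dz);
      if (!std::isfinite(Vn) || std::fabs(Vn) > 200.0)
        stop("numerical blow-up: |V| > 200 mV at cell %d, t = %.3f ms", i + 1, t + dt);
      Vprev[i] = Vi;
      V[i] = Vn;
    }

    // decay conductances, then deposit spikes detected on this step so the
    // new contribution enters from the next step onward at full weight
    for (int i = 0; i < n_cells; ++i) { ge[i] *= dec_e; gi[i] *= dec_i; }
    for (int i = 0; i < n_cells; ++i) {
      if (Vprev[i] < 0.0 && V[i] >= 0.0 && (step - last_spike[i]) >= lockout_steps) {
        last_spike[i] = step;
        spike_t.push_back(t + dt);
        spike_id.push_back(i + 1);
        int lo = edge_ptr[i], hiq = edge_ptr[i + 1];
        if (is_exc[i]) {
          for (int q = lo; q < hiq; ++q) ge[edge_tgt[q]] += edge_w[q];
        } else {
          for (int q = lo; q < hiq; ++q) gi[edge_tgt[q]] += edge_w[q];
        }
      }
    }
    if (step % 4096 == 0) checkUserInterrupt();
  }

  List out = List::create(
    _["spike_time"] = wrap(spike_t),
    _["spike_id"] = wrap(spike_id),
    _["rec_times"] = rec_times,
    _["voltages"] = vrec,
    _["final_V"] = wrap(V),
    _["final_h"] = wrap(h),
    _["final_n"] = wrap(n_),
    _["final_z"] = wrap(z));
  if (record_syn) { out["ge"] = gerec; out["gi"] = girec; }
  return out;
}
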