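#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Clock-driven integrator for the mixed NSI + sCPG network.
//
// Populations (n_per_pop AdEx neurons each, all-to-all between populations,
// none within):
//   E : excitatory half of the spiking CPG
//   I : inhibitory half of the spiking CPG (E and I mutually inhibit)
//   M : motor neuron population, driven by E (+) and I (-)
// plus a single sub-threshold leaky-integrator interneuron (NSI) whose
// displacement from rest drives graded current injections and voltage
// characteristic offsets of the spiking neurons.
//
// Units: mV, ms, pA, pF, nS (nS * mV = pA).  Explicit Euler at dt.
// Spike rule: when V_m > 0 mV -> V_m = V_reset_eff, w_adapt += b.
// The exponential term uses the *pre-step* V_m, which the reset rule keeps
// <= 0 mV, so the term is bounded and cannot overflow.

static inline double adex_dv(double V, double w, double I, double C,
                             double gL, double EL, double DeltaT,
                             double vth) {
  return (-gL * (V - EL) + gL * DeltaT * std::exp((V - vth) / DeltaT) - w + I) / C;
}

// [[Rcpp::export]]
List sim_network_cpp(double duration, double dt, double record_dt,
                     NumericVector C, NumericVector gL, NumericVector EL,
                     NumericVector DeltaT, NumericVector a,
                     NumericVector b, NumericVector tauw,
                     NumericVector vfloor,
                     double vth_default, double vreset_default,
                     NumericVector bias,    // E, I, M (pA)
                     NumericVector init_v,  // E, I, M initial V_m (mV)
                     int n_per_pop,
                     double w_ei,  // I -> E, pA per presynaptic spike (signed)
                     double w_ie,  // E -> I
                     double w_em,  // E -> M
                     double w_im,  // I -> M
                     double tau_syn, double tau_syn_m, double delay,
                     double nsi_tau, double nsi_R, double nsi_vrest,
                     double nsi_guard,
                     NumericVector nsi_input,  // pA per recording bin
                     double noise_nsi, double noise_neuron,
                     int polarity,  // +1 excitatory, -1 inhibitory
                     double w_syn,  // nS, NSI output conductance
                     bool inj_mnp, bool inj_e, bool inj_i,
                     int voltage_target,  // 0 none, 1 Vth, 2 Vreset, 3 Vm
                     bool vt_e, bool vt_i,
                     double vth_initial, double vreset_initial,
                     double disp_max, double vcm_divisor,
                     bool vm_every_step,
                     bool feedback, double fb_sc_exc, double fb_sc_inh,
                     double fb_desired, double fb_cap, double fb_window,
                     bool record_traces) {
  const int n_steps = (int)std::lround(duration / dt);
  const int steps_per_rec = (int)std::lround(record_dt / dt);
  const int n_rec = (int)std::lround(duration / record_dt);
  const int delay_steps = std::max(1, (int)std::lround(delay / dt));
  const double decay_syn = std::exp(-dt / tau_syn);
  const double decay_syn_m = std::exp(-dt / tau_syn_m);
  const int NP = n_per_pop, NTOT = 3 * NP;

  if (nsi_input.size() < n_rec)
    stop("nsi_input schedule shorter than the number of recording bins");

  std::vector<double> V(NTOT), W(NTOT, 0.0), SYN(NTOT, 0.0);
  for (int p = 0; p < 3; ++p)
    for (int j = 0; j < NP; ++j) V[p * NP + j] = init_v[p];

  double u = 0.0;  // NSI displacement from rest
  const double vref = nsi_vrest;  // reference captured at t = 0

  std::vector<int> hist_e(n_steps, 0), hist_i(n_steps, 0);
  std::vector<int> mnp_ms(n_rec, 0);
  std::vector<std::vector<double>> sp_t(3);
  std::vector<std::vector<int>> sp_id(3);

  NumericVector nsi_trace(n_rec), vcm_trace(n_rec), fb_w_trace(n_rec);
  NumericMatrix traces;
  if (record_traces) traces = NumericMatrix(n_rec, NTOT);

  double fb_conductance = 0.0;  // signed nS, updated each recording bin

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const int bin = k / steps_per_rec;

    if (k % steps_per_rec == 0) {
      nsi_trace[bin] = nsi_vrest + u;
      if (record_traces)
        for (int n = 0; n < NTOT; ++n) traces(bin, n) = V[n];
      if (feedback) {
        const int wbins = (int)std::lround(fb_window / record_dt);
        int cnt = 0;
        for (int bb = std::max(0, bin - wbins); bb < bin; ++bb) cnt += mnp_ms[bb];
        const double err = fb_desired - cnt;
        double wmag = std::fabs(err) * (err > 0 ? fb_sc_exc : fb_sc_inh);
        if (fb_cap > 0 && wmag > fb_cap) wmag = fb_cap;
        fb_conductance = (err > 0 ? 1.0 : (err < 0 ? -1.0 : 0.0)) * wmag;
        fb_w_trace[bin] = fb_conductance;
      }
    }

    // --- NSI update (noise draw order: NSI, then E, I, M neurons) ---
    const double I_in = nsi_input[bin] + norm_rand() * noise_nsi;
    u += dt / nsi_tau * (-u + nsi_R * I_in / 1000.0);  // MOhm*pA/1000 = mV
    const double v_nsi = nsi_vrest + u;
    if (v_nsi > nsi_guard)
      stop("NSI sub-threshold contract violated: V_m = %.2f mV > guard %.2f mV at t = %.1f ms",
           v_nsi, nsi_guard, t);
    if (!std::isfinite(v_nsi))
      stop("NSI integration blow-up at t = %.1f ms (dt = %g ms)", t, dt);

    double mag = std::fabs(vref - v_nsi);
    if (mag > disp_max) mag = disp_max;
    const double vcm = polarity * mag / vcm_divisor;
    if (k % steps_per_rec == 0) vcm_trace[bin] = vcm;

    const double inj = polarity * w_syn * mag;  // pA
    const double inj_m = feedback ? fb_conductance * mag : (inj_mnp ? inj : 0.0);
    const double inj_pop[3] = {inj_e ? inj : 0.0, inj_i ? inj : 0.0, inj_m};

    // --- delayed population spike counts ---
    const int cnt_e_del = (k >= delay_steps) ? hist_e[k - delay_steps] : 0;
    const int cnt_i_del = (k >= delay_steps) ? hist_i[k - delay_steps] : 0;
    const double syn_in[3] = {w_ei * cnt_i_del, w_ie * cnt_e_del,
                              w_em * cnt_e_del + w_im * cnt_i_del};

    int cnt_now[3] = {0, 0, 0};
    for (int p = 0; p < 3; ++p) {
      const bool targeted = (p == 0 && vt_e) || (p == 1 && vt_i);
      double vth = vth_default, vreset = vreset_default;
      if (p < 2 && targeted) {
        if (voltage_target == 1) vth = vth_initial + vcm;
        else if (voltage_target == 2) vreset = vreset_initial - vcm;
      }
      for (int j = 0; j < NP; ++j) {
        const int n = p * NP + j;
        SYN[n] = SYN[n] * (p == 2 ? decay_syn_m : decay_syn) + syn_in[p];
        const double nz = norm_rand() * noise_neuron;
        const double I = bias[p] + SYN[n] + nz + inj_pop[p];
        double v = V[n], w = W[n];
        bool spiked = false;
        if (v > 0.0) {  // reset carried over from an external perturbation
          v = vreset; w += b[p]; spiked = true;
        } else {
          const double vn = v + dt * adex_dv(v, w, I, C[p], gL[p], EL[p],
                                             DeltaT[p], vth);
          const double wn = w + dt / tauw[p] * (a[p] * (v - EL[p]) - w);
          v = vn; w = wn;
          if (!std::isfinite(v) || !std::isfinite(w))
            stop("AdEx integration blow-up in population %d at t = %.1f ms (dt = %g ms)",
                 p + 1, t, dt);
          if (v > 0.0) { v = vreset; w += b[p]; spiked = true; }
          if (v < vfloor[p]) v = vfloor[p];
        }
        if (p < 2 && targeted && voltage_target == 3 &&
            (vm_every_step || k % steps_per_rec == 0))
          v += vcm;
        if (!std::isfinite(v) || !std::isfinite(w))
          stop("AdEx integration blow-up in population %d at t = %.1f ms (dt = %g ms)",
               p + 1, t, dt);
        V[n] = v; W[n] = w;
        if (spiked) {
          ++cnt_now[p];
          sp_t[p].push_back(t);
          sp_id[p].push_back(j + 1);
        }
      }
    }
    hist_e[k] = cnt_now[0];
    hist_i[k] = cnt_now[1];
    mnp_ms[bin] += cnt_now[2];
  }

  List out = List::create(
      _["spike_t_e"] = wrap(sp_t[0]), _["spike_id_e"] = wrap(sp_id[0]),
      _["spike_t_i"] = wrap(sp_t[1]), _["spike_id_i"] = wrap(sp_id[1]),
      _["spike_t_m"] = wrap(sp_t[2]), _["spike_id_m"] = wrap(sp_id[2]),
      _["nsi_v"] = nsi_trace, _["vcm"] = vcm_trace,
      _["mnp_counts_ms"] = wrap(mnp_ms),
      _["fb_weight"] = fb_w_trace);
  if (record_traces) out["traces"] = traces;
  return out;
}
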