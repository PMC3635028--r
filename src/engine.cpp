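// Forward-Euler integrator for the antennal-lobe network.
//
// 90 PNs (Traub-Miles Na/K at V_T = -63 mV, rates scaled by phi = 0.5;
// transient K current) and 30 LNs (transient Ca current with inactivation
// time constant converted from seconds; Ca-dependent K; delayed rectifier
// with the squid n-gate shifted +40.25 mV), coupled by continuous-release
// fast GABA, event-triggered nicotinic ACh and the slow G-protein-coupled
// inhibitory current. Synaptic state is tracked once per presynaptic neuron
// (all efferent synapses of a cell share [O]/[R]/[G]) and summed over each
// cell's afferent list.
//
// All randomness (Poisson input events) is drawn from R's RNG so that
// set.seed() in R makes trials reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double PN_VT = -63.0, PN_PHI = 0.5, LN_KSHIFT = 40.25;

inline double xexpm(double x, double s) {
  return std::fabs(x) < 1e-7 ? s : x / (1.0 - std::exp(-x / s));
}

struct Wiring {
  // afferent (presynaptic index) lists per postsynaptic cell
  std::vector<std::vector<int>> pn_from_pn, ln_from_pn, ln_from_ln, pn_from_ln;
};

inline double envelope(double t, double t_on, double t_off, double rise,
                       double c1, double c2) {
  if (t < t_on) return 0.0;
  if (t < t_on + rise) {
    double d = t - (t_on + rise);
    return std::exp(-d * d / c1);
  }
  if (t <= t_off) return 1.0;
  return std::exp(-std::sqrt(t - t_off) / c2);
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n_pn, int n_ln,
                IntegerVector pp_pre, IntegerVector pp_post,
                IntegerVector pl_pre, IntegerVector pl_post,
                IntegerVector ll_pre, IntegerVector ll_post,
                IntegerVector lp_pre, IntegerVector lp_post,
                List cond, List stim, List phys, double dt, double duration,
                bool record_v, int v_decim) {
  // --- conductances (variant-scaled upstream) ---
  const double g_nach_pnpn = cond["g_nach_pnpn"];
  const double g_nach_pnln = cond["g_nach_pnln"];
  const double g_gaba_lnln = cond["g_gaba_lnln"];
  const double g_gaba_lnpn = cond["g_gaba_lnpn"];
  const double g_slow_lnpn = cond["g_slow_lnpn"];

  // --- physiological parameters (al_params(), possibly overridden) ---
  List ppn = phys["pn"], pln = phys["ln"], pca = phys["ca"], psyn = phys["syn"];
  List pgaba = psyn["gaba"], pnach = psyn["nach"], pslow = psyn["slow"];
  const double C_m = ppn["C_m"];
  const double pn_gL = ppn["g_L"], pn_EL = ppn["E_L"], pn_gNa = ppn["g_Na"],
               pn_ENa = ppn["E_Na"], pn_gK = ppn["g_K"], pn_EK = ppn["E_K"],
               pn_gA = ppn["g_A"];
  const double ln_Cm = pln["C_m"];
  const double ln_gL = pln["g_L"], ln_EL = pln["E_L"], ln_gCa = pln["g_Ca"],
               ln_ECa = pln["E_Ca"], ln_gCaK = pln["g_CaK"],
               ln_gK = pln["g_K"], ln_EK = pln["E_K"];
  const double ca_A = pca["A"], ca_inf = pca["Ca_inf"], ca_tau = pca["tau"];
  const double gaba_alpha = pgaba["alpha"], gaba_beta = pgaba["beta"],
               gaba_E = pgaba["E"], gaba_V0 = pgaba["V0"],
               gaba_sigma = pgaba["sigma"];
  const double nach_alpha = pnach["alpha"], nach_beta = pnach["beta"],
               nach_E = pnach["E"], syn_tmax = pnach["t_max"],
               syn_Tamp = pnach["T_amp"];
  const double r1 = pslow["r1"], r2 = pslow["r2"], r3 = pslow["r3"],
               r4 = pslow["r4"], slow_K = pslow["K"], slow_E = pslow["E"];
  const double event_refract = psyn["event_refractory"], spike_refract = 2.0;

  // --- stimulus ---
  const double bg_rate = stim["bg_rate"];           // events/s per PN
  const double bg_amp = stim["bg_amp"];             // uA per event (gain applied)
  const double odor_rate_max = stim["odor_rate_max"]; // events/s per stimulated cell
  const double odor_amp_pn = stim["odor_amp_pn"];
  const double odor_amp_ln = stim["odor_amp_ln"];
  const double t_on = stim["t_on"], t_off = stim["t_off"],
               rise = stim["rise"], c1 = stim["c1"], c2 = stim["c2"];
  const double tau_in = stim["tau_in"];
  IntegerVector stim_pn = stim["stim_pn"], stim_ln = stim["stim_ln"]; // 0-based
  NumericVector step_i_pn = stim["step_i_pn"], step_i_ln = stim["step_i_ln"];
  const double step_t0 = stim["step_t0"], step_t1 = stim["step_t1"];

  const int n_steps = (int)std::lround(duration / dt);
  const int klen = std::max(1, (int)std::lround(tau_in / dt));

  // --- afferent lists ---
  Wiring w;
  w.pn_from_pn.resize(n_pn); w.pn_from_ln.resize(n_pn);
  w.ln_from_pn.resize(n_ln); w.ln_from_ln.resize(n_ln);
  for (int e = 0; e < pp_pre.size(); ++e) w.pn_from_pn[pp_post[e]].push_back(pp_pre[e]);
  for (int e = 0; e < pl_pre.size(); ++e) w.ln_from_pn[pl_post[e]].push_back(pl_pre[e]);
  for (int e = 0; e < ll_pre.size(); ++e) w.ln_from_ln[ll_post[e]].push_back(ll_pre[e]);
  for (int e = 0; e < lp_pre.size(); ++e) w.pn_from_ln[lp_post[e]].push_back(lp_pre[e]);

  // --- state ---
  std::vector<double> pnV(n_pn, pn_EL), pn_m(n_pn), pn_h(n_pn), pn_n(n_pn),
      pn_ma(n_pn), pn_ha(n_pn);
  std::vector<double> lnV(n_ln, ln_EL), ln_m(n_ln), ln_h(n_ln), ln_mck(n_ln),
      ln_n(n_ln), ln_ca(n_ln, ca_inf);
  {
    double v = pn_EL - PN_VT;
    double am = 0.32 * xexpm(v - 13, 4), bm = 0.28 * xexpm(40 - v, 5);
    double ah = 0.128 * std::exp((17 - v) / 18.0),
           bh = 4.0 / (1.0 + std::exp((40 - v) / 5.0));
    double an = 0.032 * xexpm(v - 15, 5), bn = 0.5 * std::exp((10 - v) / 40.0);
    for (int i = 0; i < n_pn; ++i) {
      pn_m[i] = am / (am + bm); pn_h[i] = ah / (ah + bh); pn_n[i] = an / (an + bn);
      pn_ma[i] = 1.0 / (1.0 + std::exp(-(pn_EL + 60) / 8.5));
      pn_ha[i] = 1.0 / (1.0 + std::exp((pn_EL + 78) / 6.0));
    }
    double vk = ln_EL - LN_KSHIFT;
    double ank = 0.01 * xexpm(vk + 55, 10), bnk = 0.125 * std::exp(-(vk + 65) / 80.0);
    for (int i = 0; i < n_ln; ++i) {
      ln_m[i] = 1.0 / (1.0 + std::exp(-(ln_EL + 20) / 6.5));
      ln_h[i] = 1.0 / (1.0 + std::exp((ln_EL + 25) / 12.0));
      ln_mck[i] = ca_inf / (ca_inf + 2.0);
      ln_n[i] = ank / (ank + bnk);
    }
  }

  // per-presynaptic-neuron synaptic state
  std::vector<double> O_nach(n_pn, 0.0), O_gaba(n_ln, 0.0),
      R_slow(n_ln, 0.0), G_slow(n_ln, 0.0);
  std::vector<double> pn_t0(n_pn, -1e18), ln_t0(n_ln, -1e18); // last event
  std::vector<double> pn_last_spike(n_pn, -1e18), ln_last_spike(n_ln, -1e18);

  // input-event ring buffers (rectangular pulses of width tau_in)
  std::vector<double> ring_pn(n_pn * klen, 0.0), ring_ln(n_ln * klen, 0.0);
  std::vector<double> Iin_pn(n_pn, 0.0), Iin_ln(n_ln, 0.0);
  std::vector<char> pn_stim(n_pn, 0), ln_stim(n_ln, 0);
  for (int i = 0; i < stim_pn.size(); ++i) pn_stim[stim_pn[i]] = 1;
  for (int i = 0; i < stim_ln.size(); ++i) ln_stim[stim_ln[i]] = 1;

  std::vector<std::vector<double>> spk_pn(n_pn), spk_ln(n_ln);

  int n_rec = record_v ? n_steps / v_decim : 0;
  NumericMatrix v_pn_rec(record_v ? n_rec : 0, record_v ? n_pn : 0);
  NumericMatrix v_ln_rec(record_v ? n_rec : 0, record_v ? n_ln : 0);
  int rec_row = 0;

  RNGScope rng;
  const double bg_lam = bg_rate * 1e-3 * dt;

  std::vector<double> dpnV(n_pn), dlnV(n_ln);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int rpos = step % klen;
    const double env = envelope(t, t_on, t_off, rise, c1, c2);
    const double odor_lam = odor_rate_max * 1e-3 * dt * env;
    const bool step_on = (t >= step_t0 && t < step_t1);

    // ---- input events -> rectangular current pulses ----
    for (int i = 0; i < n_pn; ++i) {
      double add = 0.0;
      if (bg_lam > 0) add += bg_amp * R::rpois(bg_lam);
      if (pn_stim[i] && odor_lam > 0) add += odor_amp_pn * R::rpois(odor_lam);
      double *slot = &ring_pn[i * klen + rpos];
      Iin_pn[i] += add - *slot;
      *slot = add;
    }
    for (int i = 0; i < n_ln; ++i) {
      double add = 0.0;
      if (ln_stim[i] && odor_lam > 0) add += odor_amp_ln * R::rpois(odor_lam);
      double *slot = &ring_ln[i * klen + rpos];
      Iin_ln[i] += add - *slot;
      *slot = add;
    }

    // ---- synaptic gating (from state at time t) ----
    for (int q = 0; q < n_ln; ++q) {
      double T = 1.0 / (1.0 + std::exp(-(lnV[q] - gaba_V0) / gaba_sigma));
      O_gaba[q] += dt * (gaba_alpha * (1.0 - O_gaba[q]) * T - gaba_beta * O_gaba[q]);
      double Ts = (t >= ln_t0[q] && t <= ln_t0[q] + syn_tmax) ? syn_Tamp : 0.0;
      double Rq = R_slow[q], Gq = G_slow[q];
      R_slow[q] = Rq + dt * (r1 * (1.0 - Rq) * Ts - r2 * Rq);
      G_slow[q] = Gq + dt * (r3 * Rq - r4 * Gq);
    }
    for (int q = 0; q < n_pn; ++q) {
      double T = (t >= pn_t0[q] && t <= pn_t0[q] + syn_tmax) ? syn_Tamp : 0.0;
      O_nach[q] += dt * (nach_alpha * (1.0 - O_nach[q]) * T - nach_beta * O_nach[q]);
    }

    // ---- membrane derivatives ----
    for (int i = 0; i < n_pn; ++i) {
      const double V = pnV[i];
      double O_exc = 0.0, O_inh = 0.0, G_tot = 0.0;
      for (int q : w.pn_from_pn[i]) O_exc += O_nach[q];
      for (int q : w.pn_from_ln[i]) { O_inh += O_gaba[q]; G_tot += G_slow[q]; }
      const double g4 = G_tot * G_tot * G_tot * G_tot;
      double I_syn = g_nach_pnpn * O_exc * (V - nach_E) +
                     g_gaba_lnpn * O_inh * (V - gaba_E) +
                     g_slow_lnpn * g4 / (g4 + slow_K) * (V - slow_E);
      double I_int = pn_gNa * pn_m[i] * pn_m[i] * pn_m[i] * pn_h[i] * (V - pn_ENa) +
                     pn_gK * pn_n[i] * pn_n[i] * pn_n[i] * pn_n[i] * (V - pn_EK) +
                     pn_gA * pn_ma[i] * pn_ma[i] * pn_ma[i] * pn_ma[i] * pn_ha[i] * (V - pn_EK);
      double I_in = Iin_pn[i];
      if (step_on && step_i_pn.size() == n_pn) I_in += step_i_pn[i];
      dpnV[i] = (-pn_gL * (V - pn_EL) - I_int - I_syn + I_in) / C_m;

      // gate updates from V at time t
      const double v = V - PN_VT;
      const double am = 0.32 * xexpm(v - 13, 4), bm = 0.28 * xexpm(40 - v, 5);
      const double ah = 0.128 * std::exp((17 - v) / 18.0),
                   bh = 4.0 / (1.0 + std::exp((40 - v) / 5.0));
      const double an = 0.032 * xexpm(v - 15, 5),
                   bn = 0.5 * std::exp((10 - v) / 40.0);
      pn_m[i] += dt * PN_PHI * (am * (1.0 - pn_m[i]) - bm * pn_m[i]);
      pn_h[i] += dt * PN_PHI * (ah * (1.0 - pn_h[i]) - bh * pn_h[i]);
      pn_n[i] += dt * PN_PHI * (an * (1.0 - pn_n[i]) - bn * pn_n[i]);
      const double mainf = 1.0 / (1.0 + std::exp(-(V + 60) / 8.5));
      const double tama = 0.27 / (std::exp((V + 35.8) / 19.7) +
                                  std::exp(-(V + 79.7) / 12.7)) + 0.1;
      const double hainf = 1.0 / (1.0 + std::exp((V + 78) / 6.0));
      const double taha = (V < -63.0)
          ? 0.27 / (std::exp((V + 46) / 5.0) + std::exp(-(V + 238) / 37.5))
          : 5.1;
      pn_ma[i] += dt * (mainf - pn_ma[i]) / tama;
      pn_ha[i] += dt * (hainf - pn_ha[i]) / taha;
    }

    for (int i = 0; i < n_ln; ++i) {
      const double V = lnV[i];
      double O_exc = 0.0, O_inh = 0.0;
      for (int q : w.ln_from_pn[i]) O_exc += O_nach[q];
      for (int q : w.ln_from_ln[i]) O_inh += O_gaba[q];
      double I_syn = g_nach_pnln * O_exc * (V - nach_E) +
                     g_gaba_lnln * O_inh * (V - gaba_E);
      const double I_Ca = ln_gCa * ln_m[i] * ln_m[i] * ln_h[i] * (V - ln_ECa);
      double I_int = I_Ca + ln_gCaK * ln_mck[i] * (V - ln_EK) +
                     ln_gK * ln_n[i] * ln_n[i] * ln_n[i] * ln_n[i] * (V - ln_EK);
      double I_in = Iin_ln[i];
      if (step_on && step_i_ln.size() == n_ln) I_in += step_i_ln[i];
      dlnV[i] = (-ln_gL * (V - ln_EL) - I_int - I_syn + I_in) / ln_Cm;

      const double minf = 1.0 / (1.0 + std::exp(-(V + 20) / 6.5));
      const double taum = std::max(1.0 + (V + 30) * 0.014, 0.1);
      const double hinf = 1.0 / (1.0 + std::exp((V + 25) / 12.0));
      const double tauh = 1000.0 * (0.3 * std::exp((V - 40) / 13.0) +
                                    0.002 * std::exp(-(V - 60) / 29.0));
      const double Ca = ln_ca[i];
      ln_m[i] += dt * (minf - ln_m[i]) / taum;
      ln_h[i] += dt * (hinf - ln_h[i]) / tauh;
      ln_mck[i] += dt * (Ca / (Ca + 2.0) - ln_mck[i]) * (Ca + 2.0) / 100.0;
      const double vk = V - LN_KSHIFT;
      const double ank = 0.01 * xexpm(vk + 55, 10),
                   bnk = 0.125 * std::exp(-(vk + 65) / 80.0);
      ln_n[i] += dt * (ank * (1.0 - ln_n[i]) - bnk * ln_n[i]);
      ln_ca[i] += dt * (-ca_A * I_Ca - (Ca - ca_inf) / ca_tau);
    }

    // ---- voltage updates, spike/event detection ----
    const double t_next = (step + 1) * dt;
    for (int i = 0; i < n_pn; ++i) {
      const double Vold = pnV[i];
      pnV[i] += dt * dpnV[i];
      if (Vold < 0.0 && pnV[i] >= 0.0) {
        if (t_next - pn_t0[i] > event_refract) pn_t0[i] = t_next;
        if (t_next - pn_last_spike[i] > spike_refract) {
          pn_last_spike[i] = t_next;
          spk_pn[i].push_back(t_next);
        }
      }
      if (std::fabs(pnV[i]) > 200.0)
        stop("simulation diverged (PN %d, t = %.2f ms)", i + 1, t_next);
    }
    for (int i = 0; i < n_ln; ++i) {
      const double Vold = lnV[i];
      lnV[i] += dt * dlnV[i];
      if (Vold < 0.0 && lnV[i] >= 0.0) {
        if (t_next - ln_t0[i] > event_refract) ln_t0[i] = t_next;
        if (t_next - ln_last_spike[i] > spike_refract) {
          ln_last_spike[i] = t_next;
          spk_ln[i].push_back(t_next);
        }
      }
      if (std::fabs(lnV[i]) > 200.0)
        stop("simulation diverged (LN %d, t = %.2f ms)", i + 1, t_next);
    }

    if (record_v && (step + 1) % v_decim == 0 && rec_row < n_rec) {
      for (int i = 0; i < n_pn; ++i) v_pn_rec(rec_row, i) = pnV[i];
      for (int i = 0; i < n_ln; ++i) v_ln_rec(rec_row, i) = lnV[i];
      ++rec_row;
    }
  }

  List sp(n_pn), sl(n_ln);
  for (int i = 0; i < n_pn; ++i) sp[i] = NumericVector(spk_pn[i].begin(), spk_pn[i].end());
  for (int i = 0; i < n_ln; ++i) sl[i] = NumericVector(spk_ln[i].begin(), spk_ln[i].end());

  List out = List::create(_["spikes_pn"] = sp, _["spikes_ln"] = sl);
  if (record_v) {
    out["v_pn"] = v_pn_rec;
    out["v_ln"] = v_ln_rec;
    out["v_dt"] = dt * v_decim;
  }
  return out;
}
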