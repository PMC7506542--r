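// Fixed-timestep integrator for the CA3 microcircuit.
//
// The network is flattened by the R side into struct-of-arrays form:
//   * one entry per compartment (voltage, gating states, absolute channel
//     conductances in uS, membrane capacitance in nF, axial neighbours),
//   * one entry per synaptic "channel" (a double-exponential conductance
//     shared by all synapses with identical kinetics on one compartment),
//   * exogenous events (background Poisson + medial-septal volleys) as a
//     time-sorted table, and network edges as a CSR adjacency over cells.
//
// Units: mV, ms, nF, uS, nA, mM.  Gating uses exponential-Euler updates;
// the voltage update is exponential-Euler on the diagonal with axial and
// synaptic terms evaluated at the previous step, which is stable at the
// default dt = 0.1 ms for these electrotonically compact cells.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// x/(1 - exp(-x/k)) with the removable singularity at x = 0 patched.
static inline double trap(double x, double k) {
  if (std::fabs(x / k) < 1e-6) return k + x / 2.0;
  return x / (1.0 - std::exp(-x / k));
}

// Hodgkin-Huxley rate functions (Traub-lineage kinetics; see package docs).
static inline double naf_am(double v) { return 0.32 * trap(v + 54.0, 4.0); }
static inline double naf_bm(double v) { return 0.28 * trap(-(v + 27.0), 5.0); }
static inline double naf_ah(double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); }
static inline double naf_bh(double v) { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); }
static inline double kdr_an(double v) { return 0.032 * trap(v + 52.0, 5.0); }
static inline double kdr_bn(double v) { return 0.5 * std::exp(-(v + 57.0) / 40.0); }
// A-type K+ (transient): steady states and fixed time constants.
static inline double ka_ainf(double v) { return 1.0 / (1.0 + std::exp(-(v + 25.0) / 8.0)); }
static inline double ka_binf(double v) { return 1.0 / (1.0 + std::exp((v + 70.0) / 6.0)); }
static const double KA_TAU_A = 1.0, KA_TAU_B = 15.0;
// H-current: activates with hyperpolarization.
static inline double ih_rinf(double v) { return 1.0 / (1.0 + std::exp((v + 84.0) / 10.2)); }
static inline double ih_taur(double v) { return 30.0 + 170.0 / std::cosh((v + 84.0) / 15.0); }
// High-threshold Ca (L-type), power 2.
static inline double cal_ac(double v) { return 1.6 / (1.0 + std::exp(-0.072 * (v - 5.0))); }
static inline double cal_bc(double v) { return 0.02 * trap(-(v + 8.9), 5.0); }

static const double E_NA = 55.0, E_K = -90.0, E_H = -30.0, E_CA = 120.0;
static const double CA_REST = 5e-5;   // mM
static const double CA_TAU = 80.0;    // ms
static const double KCA_KD = 0.005;   // mM half-activation of KCa

// Jahr-Stevens magnesium block of the NMDA conductance.
static inline double mgblock(double v, double mg) {
  return 1.0 / (1.0 + (mg / 3.57) * std::exp(-0.062 * v));
}

// Voltage-indexed lookup tables for gating updates: for each gating
// variable we tabulate the steady state and the exponential-Euler factor
// (1 - exp(-dt/tau)) on a fixed voltage grid and interpolate linearly.
struct GateTab {
  static const int N = 3601;
  double vmin, dv;
  std::vector<double> xinf, efac;
  GateTab() : vmin(-140.0), dv(0.06), xinf(N), efac(N) {}
  template <class FInf, class FTau>
  void build(FInf finf, FTau ftau, double dt) {
    for (int i = 0; i < N; ++i) {
      double v = vmin + i * dv;
      xinf[i] = finf(v);
      efac[i] = 1.0 - std::exp(-dt / ftau(v));
    }
  }
  inline void step(double v, double& x) const {
    double u = (v - vmin) / dv;
    if (u < 0) u = 0;
    if (u > N - 2) u = N - 2;
    int i = (int)u;
    double f = u - i;
    double xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    double ef = efac[i] + f * (efac[i + 1] - efac[i]);
    x += (xi - x) * ef;
  }
};

// [[Rcpp::export]]
List sim_core_run(List net, List cfg) {
  // --- compartments ---
  NumericVector cm    = net["cm"];       // nF
  NumericVector gleak = net["gleak"];    // uS
  NumericVector eleak = net["eleak"];    // mV
  NumericVector gnaf  = net["gnaf"];
  NumericVector gkdr  = net["gkdr"];
  NumericVector gka   = net["gka"];
  NumericVector gih   = net["gih"];
  NumericVector gcal  = net["gcal"];
  NumericVector gkca  = net["gkca"];
  NumericVector caalpha = net["ca_alpha"];  // mM per nA*ms
  IntegerVector nb_ptr = net["nb_ptr"];     // axial CSR, 0-based
  IntegerVector nb_idx = net["nb_idx"];
  NumericVector nb_g   = net["nb_g"];       // uS

  // --- cells ---
  IntegerVector soma   = net["soma_comp"];  // 0-based soma comp per cell
  IntegerVector lfp_pos = net["lfp_pos"];   // distal apical comps (PYR)
  IntegerVector lfp_neg = net["lfp_neg"];   // basal comps (PYR)

  // --- synaptic channels ---
  NumericVector ch_tau1 = net["ch_tau1"];
  NumericVector ch_tau2 = net["ch_tau2"];
  NumericVector ch_e    = net["ch_e"];
  IntegerVector ch_comp = net["ch_comp"];
  IntegerVector ch_nmda = net["ch_nmda"];

  // --- exogenous events, sorted by time ---
  NumericVector ev_time = net["ev_time"];
  IntegerVector ev_ch   = net["ev_ch"];
  NumericVector ev_w    = net["ev_w"];      // uS

  // --- network adjacency over cells (spike -> channel deliveries) ---
  IntegerVector adj_ptr = net["adj_ptr"];
  IntegerVector adj_ch  = net["adj_ch"];
  NumericVector adj_w   = net["adj_w"];     // uS

  // --- current clamps ---
  IntegerVector ic_comp  = net["ic_comp"];
  NumericVector ic_amp   = net["ic_amp"];   // nA
  NumericVector ic_start = net["ic_start"];
  NumericVector ic_end   = net["ic_end"];

  const double dt = as<double>(cfg["dt"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int rec_every = as<int>(cfg["record_every"]);   // LFP decimation
  const int delay_steps = as<int>(cfg["delay_steps"]);
  const double thresh = as<double>(cfg["spike_threshold"]);
  const double lockout = as<double>(cfg["lockout_ms"]);
  const double mg = as<double>(cfg["mg"]);
  NumericVector v_init = cfg["v_init"];
  IntegerVector rec_v = cfg["record_v_comps"];          // 0-based, may be empty

  GateTab tab_m, tab_h, tab_n, tab_a, tab_b, tab_r, tab_c;
  tab_m.build([](double v) { return naf_am(v) / (naf_am(v) + naf_bm(v)); },
              [](double v) { return 1.0 / (naf_am(v) + naf_bm(v)); }, dt);
  tab_h.build([](double v) { return naf_ah(v) / (naf_ah(v) + naf_bh(v)); },
              [](double v) { return 1.0 / (naf_ah(v) + naf_bh(v)); }, dt);
  tab_n.build([](double v) { return kdr_an(v) / (kdr_an(v) + kdr_bn(v)); },
              [](double v) { return 1.0 / (kdr_an(v) + kdr_bn(v)); }, dt);
  tab_a.build([](double v) { return ka_ainf(v); },
              [](double v) { (void)v; return KA_TAU_A; }, dt);
  tab_b.build([](double v) { return ka_binf(v); },
              [](double v) { (void)v; return KA_TAU_B; }, dt);
  tab_r.build([](double v) { return ih_rinf(v); },
              [](double v) { return ih_taur(v); }, dt);
  tab_c.build([](double v) { return cal_ac(v) / (cal_ac(v) + cal_bc(v)); },
              [](double v) { return 1.0 / (cal_ac(v) + cal_bc(v)); }, dt);

  const int n_comp = cm.size();
  const int n_cell = soma.size();
  const int n_ch = ch_comp.size();
  const int n_lfp = lfp_pos.size();

  // state
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> v_prev(v.begin(), v.end());
  std::vector<double> m(n_comp), h(n_comp), n_(n_comp), a(n_comp), b(n_comp),
      r(n_comp), c2(n_comp), ca(n_comp, CA_REST);
  for (int i = 0; i < n_comp; ++i) {
    double vi = v[i];
    m[i] = naf_am(vi) / (naf_am(vi) + naf_bm(vi));
    h[i] = naf_ah(vi) / (naf_ah(vi) + naf_bh(vi));
    n_[i] = kdr_an(vi) / (kdr_an(vi) + kdr_bn(vi));
    a[i] = ka_ainf(vi);
    b[i] = ka_binf(vi);
    r[i] = ih_rinf(vi);
    c2[i] = cal_ac(vi) / (cal_ac(vi) + cal_bc(vi));
  }

  // synapse double-exponential state and per-channel decay/normalization
  std::vector<double> sA(n_ch, 0.0), sB(n_ch, 0.0), dec1(n_ch), dec2(n_ch),
      norm(n_ch);
  for (int j = 0; j < n_ch; ++j) {
    double t1 = ch_tau1[j], t2 = ch_tau2[j];
    dec1[j] = std::exp(-dt / t1);
    dec2[j] = std::exp(-dt / t2);
    double tp = t1 * t2 / (t2 - t1) * std::log(t2 / t1);
    norm[j] = 1.0 / (std::exp(-tp / t2) - std::exp(-tp / t1));
  }

  // spike delivery ring buffer: pending presynaptic cell ids per step offset
  std::vector<std::vector<int> > ring(delay_steps + 1);
  std::vector<double> last_spike(n_cell, -1e9);

  std::vector<int> sp_cell;
  std::vector<double> sp_time;
  sp_cell.reserve(1 << 16);
  sp_time.reserve(1 << 16);

  const int n_rec = n_steps / rec_every;
  NumericVector lfp(n_rec);
  NumericMatrix vtr(rec_v.size() > 0 ? n_rec : 0, rec_v.size());

  std::vector<double> gsyn(n_comp), gesyn(n_comp), g_chan(n_comp),
      ge_chan(n_comp), v_mid(n_comp);
  long ev_i = 0;
  const long n_ev = ev_time.size();

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // deliver exogenous events falling in (t - dt, t]
    while (ev_i < n_ev && ev_time[ev_i] <= t) {
      int j = ev_ch[ev_i];
      double w = ev_w[ev_i] * norm[j];
      sA[j] += w;
      sB[j] += w;
      ++ev_i;
    }
    // deliver delayed network spikes
    std::vector<int>& due = ring[step % (delay_steps + 1)];
    for (size_t q = 0; q < due.size(); ++q) {
      int pre = due[q];
      for (int e = adj_ptr[pre]; e < adj_ptr[pre + 1]; ++e) {
        int j = adj_ch[e];
        double w = adj_w[e] * norm[j];
        sA[j] += w;
        sB[j] += w;
      }
    }
    due.clear();

    // synapse decay and per-compartment conductance accumulation
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(gesyn.begin(), gesyn.end(), 0.0);
    for (int j = 0; j < n_ch; ++j) {
      sA[j] *= dec1[j];
      sB[j] *= dec2[j];
      double g = sB[j] - sA[j];
      if (g <= 0.0) continue;
      if (ch_nmda[j]) g *= mgblock(v_prev[ch_comp[j]], mg);
      gsyn[ch_comp[j]] += g;
      gesyn[ch_comp[j]] += g * ch_e[j];
    }

    // current clamps
    std::vector<double> iinj;
    if (ic_comp.size() > 0) {
      iinj.assign(n_comp, 0.0);
      for (int q = 0; q < ic_comp.size(); ++q)
        if (t >= ic_start[q] && t < ic_end[q]) iinj[ic_comp[q]] += ic_amp[q];
    }

    // membrane update
    for (int i = 0; i < n_comp; ++i) {
      double vi = v_prev[i];

      // gating (exponential Euler via voltage-indexed tables)
      if (gnaf[i] > 0.0) {
        tab_m.step(vi, m[i]);
        tab_h.step(vi, h[i]);
      }
      if (gkdr[i] > 0.0) tab_n.step(vi, n_[i]);
      if (gka[i] > 0.0) {
        tab_a.step(vi, a[i]);
        tab_b.step(vi, b[i]);
      }
      if (gih[i] > 0.0) tab_r.step(vi, r[i]);
      double ica = 0.0;
      if (gcal[i] > 0.0) {
        tab_c.step(vi, c2[i]);
        ica = gcal[i] * c2[i] * c2[i] * (vi - E_CA);
        ca[i] += (-caalpha[i] * ica - (ca[i] - CA_REST) / CA_TAU) * dt;
        if (ca[i] < 0.0) ca[i] = 0.0;
      }

      // conductance totals (all channels ohmic; outward positive)
      double g = gleak[i], ge = gleak[i] * eleak[i];
      if (gnaf[i] > 0.0) {
        double gx = gnaf[i] * m[i] * m[i] * m[i] * h[i];
        g += gx; ge += gx * E_NA;
      }
      if (gkdr[i] > 0.0) {
        double n2 = n_[i] * n_[i];
        double gx = gkdr[i] * n2 * n2;
        g += gx; ge += gx * E_K;
      }
      if (gka[i] > 0.0) {
        double gx = gka[i] * a[i] * b[i];
        g += gx; ge += gx * E_K;
      }
      if (gih[i] > 0.0) {
        double gx = gih[i] * r[i];
        g += gx; ge += gx * E_H;
      }
      if (gcal[i] > 0.0) {
        double gx = gcal[i] * c2[i] * c2[i];
        g += gx; ge += gx * E_CA;
        double gk = gkca[i] * ca[i] / (ca[i] + KCA_KD);
        g += gk; ge += gk * E_K;
      }
      g_chan[i] = g;
      ge_chan[i] = ge;
      // predictor: axial coupling with neighbour voltages from the
      // previous step
      for (int q = nb_ptr[i]; q < nb_ptr[i + 1]; ++q) {
        g += nb_g[q];
        ge += nb_g[q] * v_prev[nb_idx[q]];
      }
      g += gsyn[i];
      ge += gesyn[i];
      if (!iinj.empty()) ge += iinj[i];

      double vinf = ge / g;
      v[i] = vinf + (v_prev[i] - vinf) * std::exp(-dt * g / cm[i]);
    }

    // corrector: re-evaluate the voltage-dependent couplings (axial
    // neighbours, NMDA magnesium block) at the predicted midpoint voltages
    // and redo the membrane update (Heun-type second order)
    for (int i = 0; i < n_comp; ++i)
      v_mid[i] = 0.5 * (v_prev[i] + v[i]);
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(gesyn.begin(), gesyn.end(), 0.0);
    for (int j = 0; j < n_ch; ++j) {
      double gj = sB[j] - sA[j];
      if (gj <= 0.0) continue;
      if (ch_nmda[j]) gj *= mgblock(v_mid[ch_comp[j]], mg);
      gsyn[ch_comp[j]] += gj;
      gesyn[ch_comp[j]] += gj * ch_e[j];
    }
    for (int i = 0; i < n_comp; ++i) {
      double g = g_chan[i], ge = ge_chan[i];
      for (int q = nb_ptr[i]; q < nb_ptr[i + 1]; ++q) {
        g += nb_g[q];
        ge += nb_g[q] * v_mid[nb_idx[q]];
      }
      g += gsyn[i];
      ge += gesyn[i];
      if (!iinj.empty()) ge += iinj[i];
      double vinf = ge / g;
      v[i] = vinf + (v_prev[i] - vinf) * std::exp(-dt * g / cm[i]);
    }

    // spike detection at somas: upward threshold crossing with lockout
    for (int cidx = 0; cidx < n_cell; ++cidx) {
      int sc = soma[cidx];
      if (v_prev[sc] < thresh && v[sc] >= thresh &&
          t - last_spike[cidx] >= lockout) {
        last_spike[cidx] = t;
        sp_cell.push_back(cidx);
        sp_time.push_back(t + dt);
        ring[(step + delay_steps) % (delay_steps + 1)].push_back(cidx);
      }
    }

    std::swap(v, v_prev);  // v_prev now holds the new state

    // recording (post-update state)
    if ((step + 1) % rec_every == 0) {
      int k = (step + 1) / rec_every - 1;
      if (n_lfp > 0) {
        double s = 0.0;
        for (int q = 0; q < n_lfp; ++q)
          s += v_prev[lfp_pos[q]] - v_prev[lfp_neg[q]];
        lfp[k] = s / n_lfp;
      }
      for (int q = 0; q < rec_v.size(); ++q) vtr(k, q) = v_prev[rec_v[q]];
    }

    if ((step & 1023) == 0) {
      for (int cidx = 0; cidx < n_cell; ++cidx)
        if (!std::isfinite(v_prev[soma[cidx]]))
          stop("integration failure: non-finite voltage in cell %d at t = %.1f ms",
               cidx + 1, t);
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
      _["spike_cell"] = wrap(sp_cell), _["spike_time"] = wrap(sp_time),
      _["lfp"] = lfp, _["v_traces"] = vtr);
}

// Double-exponential synaptic conductance, peak-normalized so that a unit
// event reaches exactly gmax at its peak time.
// [[Rcpp::export]]
NumericVector dblexp_eval(NumericVector t, double tau1, double tau2,
                          double gmax) {
  double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  double A = 1.0 / (std::exp(-tp / tau2) - std::exp(-tp / tau1));
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i) {
    double ti = t[i];
    out[i] = ti < 0 ? 0.0
                    : gmax * A * (std::exp(-ti / tau2) - std::exp(-ti / tau1));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nmda_block_cpp(NumericVector v, double mg) {
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = mgblock(v[i], mg);
  return out;
}
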