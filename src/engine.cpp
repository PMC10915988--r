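// Fixed-step network integrator for single-compartment Hodgkin-Huxley neurons
// with AMPA / phasic GABA-A / tonic GABA-A / GABA-B (G-protein cascade) synapses.
// Gating uses exponential Euler with voltage-indexed lookup tables; the membrane
// update is exponential Euler on the full (ohmic) conductance balance, which is
// unconditionally stable at the spike-time conductance peaks.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rate functions. V in mV, time constants in ms. Cortical spike kinetics are
// expressed relative to a per-cell threshold shift VT (Traub-style); thalamic
// T-current kinetics come in a relay (TC) and a reticular (NRT) variant.
// ---------------------------------------------------------------------------

static inline double vtrap(double x, double y) {
  // x/(exp(x/y)-1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// Na activation (argument is V - VT)
static void na_m(double v, double &inf, double &tau) {
  double a = 0.32 * vtrap(13.0 - v, 4.0);
  double b = 0.28 * vtrap(v - 40.0, 5.0);
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static void na_h(double v, double &inf, double &tau) {
  double a = 0.128 * std::exp((17.0 - v) / 18.0);
  double b = 4.0 / (1.0 + std::exp((40.0 - v) / 5.0));
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static void k_n(double v, double &inf, double &tau) {
  double a = 0.032 * vtrap(15.0 - v, 5.0);
  double b = 0.5 * std::exp((10.0 - v) / 40.0);
  inf = a / (a + b); tau = 1.0 / (a + b);
}
// Slow non-inactivating K (adaptation), tau_max fixed at 1000 ms
static void m_p(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  tau = 1000.0 / (3.3 * std::exp((v + 35.0) / 20.0) + std::exp(-(v + 35.0) / 20.0));
}
// T-type Ca2+, thalamocortical relay variant (36 C)
static void tc_tm(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 59.0) / 6.2));
  tau = (0.612 + 1.0 / (std::exp(-(v + 131.6) / 16.7) + std::exp((v + 16.8) / 18.2))) / 3.74;
  if (tau < 0.05) tau = 0.05;
}
static void tc_th(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp((v + 83.0) / 4.0));
  tau = (30.8 + (211.4 + std::exp((v + 115.2) / 5.0)) / (1.0 + std::exp((v + 86.0) / 3.2))) / 3.73;
  if (tau < 1.0) tau = 1.0;
}
// T-type Ca2+, reticular variant
static void nrt_tm(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4));
  tau = (1.0 + 0.33 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 102.0) / 15.0)));
  if (tau < 0.05) tau = 0.05;
}
static void nrt_th(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
  tau = (22.7 + 0.27 / (std::exp((v + 48.0) / 4.0) + std::exp(-(v + 407.0) / 50.0)));
  if (tau < 1.0) tau = 1.0;
}
// Hyperpolarization-activated cation current (single gate)
static void h_h(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
  tau = 1.0 / (std::exp(-14.59 - 0.086 * v) + std::exp(-1.87 + 0.0701 * v));
  if (tau < 1.0) tau = 1.0;
}
// Persistent Na+ (activation treated as instantaneous)
static void nap_m(double v, double &inf, double &tau) {
  inf = 1.0 / (1.0 + std::exp(-(v + 55.7) / 7.7));
  tau = 0.2;
}

typedef void (*rate_fn)(double, double&, double&);

// fast exp(-x) for x >= 0 via a dense lookup table with linear interpolation;
// relative error < 1e-7 over [0, 30), exact 0 beyond
struct NegExpTable {
  std::vector<double> tab;
  static const int N = 30000;
  NegExpTable() {
    tab.resize(N + 1);
    for (int i = 0; i <= N; ++i) tab[i] = std::exp(-i * (30.0 / N));
  }
  inline double operator()(double x) const {
    if (x <= 0.0) return 1.0;
    double u = x * (N / 30.0);
    if (u >= N) return 0.0;
    int i = (int)u;
    double w = u - i;
    return tab[i] + w * (tab[i + 1] - tab[i]);
  }
};
static const NegExpTable fexp_neg;

struct GateTable {
  // inf and (1 - exp(-dt/tau)) sampled on a uniform voltage grid
  std::vector<double> inf, fac;
  double v0, dv_inv;
  int n;
  void build(rate_fn f, double dt, double vmin = -130.0, double vmax = 70.0, double dv = 0.05) {
    v0 = vmin; dv_inv = 1.0 / dv;
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    inf.resize(n); fac.resize(n);
    for (int i = 0; i < n; ++i) {
      double x, tau;
      f(vmin + i * dv, x, tau);
      inf[i] = x;
      fac[i] = 1.0 - std::exp(-dt / tau);
    }
  }
  inline void look(double v, double &xi, double &xf) const {
    double u = (v - v0) * dv_inv;
    if (u <= 0.0) { xi = inf[0]; xf = fac[0]; return; }
    if (u >= n - 1) { xi = inf[n - 1]; xf = fac[n - 1]; return; }
    int i = (int)u;
    double w = u - i;
    xi = inf[i] + w * (inf[i + 1] - inf[i]);
    xf = fac[i] + w * (fac[i + 1] - fac[i]);
  }
};

// GABA-B G-protein cascade constants (receptor activation r, G-protein s,
// conductance ~ s^4/(s^4 + KD)): standard two-stage scheme whose fourth-power
// nonlinearity makes the slow IPSP burst-selective.
static const double GB_K1 = 0.52;    // /mM/ms
static const double GB_K2 = 0.0013;  // /ms
static const double GB_K3 = 0.098;   // /ms
static const double GB_K4 = 0.033;   // /ms
static const double GB_KD = 100.0;
static const double GB_TDUR = 0.9;   // transmitter pulse duration, ms
static const double GB_TCONC = 0.5;  // transmitter pulse concentration, mM

// parameter matrix column indices (keep in sync with R/engine.R)
enum {
  P_C = 0, P_GNA, P_GK, P_GLEAK, P_ELEAK, P_GKL, P_GT, P_GH, P_GCAN, P_GNAP,
  P_GM, P_VT, P_GEGA, P_EK, P_ENA, P_ECA, P_EH, P_ECAN, P_ECL, P_TAUCA,
  P_KCA, P_GGB, P_NOISERATE, P_NOISEW, P_TKIN, P_NCOL
};

struct EventSlot { int tgt; int rec; double w; };

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix par, IntegerVector is_cortical_exc,
                IntegerVector conn_ptr, IntegerVector conn_tgt,
                IntegerVector conn_rec, NumericVector conn_w,
                IntegerVector conn_dsteps,
                List pert,            // onset_ms, kind, idx (list of int vecs), scale
                double dt, double duration, int seed,
                IntegerVector record_ids,
                NumericVector i_inj,  // amp (uA/cm2), t_on, t_off (applied to all cells)
                double v_init_mean, double v_init_sd) {
  const int N = par.nrow();
  const int nsteps = (int)std::llround(duration / dt);
  const int eeg_stride = std::max(1, (int)std::llround(1.0 / dt)); // 1 kHz

  // --- tables -------------------------------------------------------------
  GateTable T_nam, T_nah, T_kn, T_mp, T_tcm, T_tch, T_nrm, T_nrh, T_hh, T_nap;
  T_nam.build(na_m, dt);  T_nah.build(na_h, dt);  T_kn.build(k_n, dt);
  T_mp.build(m_p, dt);    T_tcm.build(tc_tm, dt); T_tch.build(tc_th, dt);
  T_nrm.build(nrt_tm, dt); T_nrh.build(nrt_th, dt); T_hh.build(h_h, dt);
  T_nap.build(nap_m, dt);

  // --- state --------------------------------------------------------------
  std::vector<double> V(N), m(N), h(N), n(N), p(N), mT(N), hT(N), hH(N),
      mCAN(N), Ca(N, 5e-5), lastspk(N, -1e9);
  // synaptic gates: bi-exponential pairs (rise, decay) + GABA-B cascade
  std::vector<double> ga_r(N, 0), ga_d(N, 0), gg_r(N, 0), gg_d(N, 0);
  std::vector<double> gb_rr(N, 0), gb_s(N, 0), gb_T(N, 0);
  // per-neuron receptor multipliers (perturbation surface)
  std::vector<double> mult_ampa(N, 1.0), mult_gabaa(N, 1.0), mult_gabab(N, 1.0);

  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 1013904223ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // copy mutable intrinsic conductances (perturbations scale these)
  std::vector<double> gKL(N), gT(N), gCAN(N), gEGA(N), gGB(N);
  for (int i = 0; i < N; ++i) {
    gKL[i] = par(i, P_GKL); gT[i] = par(i, P_GT); gCAN[i] = par(i, P_GCAN);
    gEGA[i] = par(i, P_GEGA); gGB[i] = par(i, P_GGB);
    V[i] = v_init_mean + v_init_sd * (2.0 * unif(rng) - 1.0);
    double vt = V[i] - par(i, P_VT), xi, xf;
    T_nam.look(vt, xi, xf); m[i] = xi;
    T_nah.look(vt, xi, xf); h[i] = xi;
    T_kn.look(vt, xi, xf);  n[i] = xi;
    T_mp.look(V[i], xi, xf); p[i] = xi;
    if (par(i, P_TKIN) < 0.5) {
      T_tcm.look(V[i], xi, xf); mT[i] = xi;
      T_tch.look(V[i], xi, xf); hT[i] = xi;
    } else {
      T_nrm.look(V[i], xi, xf); mT[i] = xi;
      T_nrh.look(V[i], xi, xf); hT[i] = xi;
    }
    T_hh.look(V[i], xi, xf); hH[i] = xi;
    mCAN[i] = 0.0;
  }

  // --- synaptic constants ---------------------------------------------------
  const double ampa_tr = 0.5, ampa_td = 2.5, gabaa_tr = 0.5, gabaa_td = 8.0;
  const double f_ar = std::exp(-dt / ampa_tr), f_ad = std::exp(-dt / ampa_td);
  const double f_gr = std::exp(-dt / gabaa_tr), f_gd = std::exp(-dt / gabaa_td);
  // normalize bi-exponential peak to 1
  auto peaknorm = [](double tr, double td) {
    double tp = tr * td / (td - tr) * std::log(td / tr);
    return 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  };
  const double norm_a = peaknorm(ampa_tr, ampa_td), norm_g = peaknorm(gabaa_tr, gabaa_td);
  const double f_gb_r0 = std::exp(-GB_K2 * dt);          // r decay when T = 0
  const double f_gb_s = std::exp(-GB_K4 * dt);
  const double f_can = 1.0 - std::exp(-dt / 160.0);      // fixed tau_CAN
  const double can_half = 2.4e-4;                        // mM, half-activation of I_CAN

  // --- event machinery ------------------------------------------------------
  int max_delay = 1;
  for (int k = 0; k < conn_dsteps.size(); ++k)
    if (conn_dsteps[k] + 1 > max_delay) max_delay = conn_dsteps[k] + 1;
  // GABA-B transmitter-off events reuse the ring: need room for pulse duration
  int tdur_steps = std::max(1, (int)std::llround(GB_TDUR / dt));
  int ring_len = max_delay + tdur_steps + 2;
  std::vector< std::vector<EventSlot> > ring(ring_len);

  // background drive: next-event times per neuron
  std::vector<double> t_noise(N);
  for (int i = 0; i < N; ++i) {
    double r = par(i, P_NOISERATE);
    t_noise[i] = (r > 0) ? -std::log(1.0 - unif(rng)) * 1000.0 / r : 1e18;
  }

  // --- perturbations --------------------------------------------------------
  NumericVector pert_onset = pert["onset_ms"];
  IntegerVector pert_kind = pert["kind"];
  List pert_idx = pert["idx"];
  NumericVector pert_scale = pert["scale"];
  int npert = pert_onset.size(), next_pert = 0;
  // sort by onset (caller guarantees sorted; enforce)
  for (int a = 1; a < npert; ++a)
    if (pert_onset[a] < pert_onset[a - 1]) stop("perturbations must be sorted by onset");

  // --- injection ------------------------------------------------------------
  int ninj = i_inj.size() / 3;

  // --- recorders ------------------------------------------------------------
  std::vector<int> spk_id; std::vector<double> spk_t;
  spk_id.reserve(1 << 16); spk_t.reserve(1 << 16);
  int n_eeg = nsteps / eeg_stride;
  NumericVector eeg(n_eeg);
  int nrec = record_ids.size();
  NumericMatrix vrec(nrec > 0 ? n_eeg : 0, nrec);

  double eeg_acc = 0.0;
  int check_every = (int)std::llround(5.0 / dt); // finite check every 5 ms

  // ---------------------------------------------------------------------------
  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    // perturbations becoming active
    while (next_pert < npert && pert_onset[next_pert] <= t + 1e-9) {
      IntegerVector ids = pert_idx[next_pert];
      double sc = pert_scale[next_pert];
      int kind = pert_kind[next_pert];
      for (int q = 0; q < ids.size(); ++q) {
        int i = ids[q];
        switch (kind) {
          case 0: gKL[i] *= sc; break;
          case 1: gT[i] *= sc; break;
          case 2: gCAN[i] *= sc; break;
          case 3: gEGA[i] *= sc; break;
          case 4: mult_ampa[i] *= sc; break;
          case 5: mult_gabaa[i] *= sc; break;
          case 6: mult_gabab[i] *= sc; break;
          default: stop("unknown perturbation kind");
        }
      }
      ++next_pert;
    }

    // deliver events due this step
    std::vector<EventSlot> &due = ring[step % ring_len];
    for (size_t e = 0; e < due.size(); ++e) {
      const EventSlot &ev = due[e];
      switch (ev.rec) {
        case 0: ga_r[ev.tgt] += ev.w; ga_d[ev.tgt] += ev.w; break;      // AMPA
        case 1: gg_r[ev.tgt] += ev.w; gg_d[ev.tgt] += ev.w; break;      // GABA-A
        case 2: gb_T[ev.tgt] += ev.w; break;                            // GABA-B T on
        case 3: gb_T[ev.tgt] -= ev.w; if (gb_T[ev.tgt] < 0) gb_T[ev.tgt] = 0; break;
      }
    }
    due.clear();

    // injected current active?
    double inj_now = 0.0;
    for (int q = 0; q < ninj; ++q)
      if (t >= i_inj[3 * q + 1] && t < i_inj[3 * q + 2]) inj_now += i_inj[3 * q];

    double eeg_step = 0.0;

    for (int i = 0; i < N; ++i) {
      // background drive
      while (t_noise[i] <= t) {
        double w = par(i, P_NOISEW);
        ga_r[i] += w; ga_d[i] += w;
        t_noise[i] += -std::log(1.0 - unif(rng)) * 1000.0 / par(i, P_NOISERATE);
      }

      double v = V[i];
      double vt = v - par(i, P_VT);
      double xi, xf;

      // gating updates (exponential Euler via tables)
      T_nam.look(vt, xi, xf); m[i] += (xi - m[i]) * xf;
      T_nah.look(vt, xi, xf); h[i] += (xi - h[i]) * xf;
      T_kn.look(vt, xi, xf);  n[i] += (xi - n[i]) * xf;
      double gM = par(i, P_GM);
      if (gM > 0) { T_mp.look(v, xi, xf); p[i] += (xi - p[i]) * xf; }
      double iT = 0.0;
      if (gT[i] > 0) {
        if (par(i, P_TKIN) < 0.5) {
          T_tcm.look(v, xi, xf); mT[i] += (xi - mT[i]) * xf;
          T_tch.look(v, xi, xf); hT[i] += (xi - hT[i]) * xf;
        } else {
          T_nrm.look(v, xi, xf); mT[i] += (xi - mT[i]) * xf;
          T_nrh.look(v, xi, xf); hT[i] += (xi - hT[i]) * xf;
        }
      }
      if (par(i, P_GH) > 0) { T_hh.look(v, xi, xf); hH[i] += (xi - hH[i]) * xf; }

      // calcium and CAN gate
      double gt_eff = gT[i] * mT[i] * mT[i] * hT[i];
      iT = gt_eff * (v - par(i, P_ECA));
      if (par(i, P_KCA) > 0) {
        double drive = -par(i, P_KCA) * iT;
        if (drive < 0) drive = 0;
        Ca[i] += dt * (drive + (5e-5 - Ca[i]) / par(i, P_TAUCA));
        if (Ca[i] < 1e-9) Ca[i] = 1e-9;
      }
      if (gCAN[i] > 0) {
        double c2 = Ca[i] * Ca[i];
        double caninf = c2 / (c2 + can_half * can_half);
        mCAN[i] += (caninf - mCAN[i]) * f_can;
      }

      // synaptic conductances (density units, mS/cm2)
      double gampa = mult_ampa[i] * norm_a * (ga_d[i] - ga_r[i]);
      double ggabaa = mult_gabaa[i] * norm_g * (gg_d[i] - gg_r[i]);
      if (gampa < 0) gampa = 0;
      if (ggabaa < 0) ggabaa = 0;
      // GABA-B cascade
      double gb = 0.0;
      if (gGB[i] > 0) {
        double Tc = gb_T[i] * GB_TCONC;
        if (Tc > 0) {
          double k1t = GB_K1 * Tc;
          double rinf = k1t / (k1t + GB_K2);
          double fr = 1.0 - std::exp(-(k1t + GB_K2) * dt);
          gb_rr[i] += (rinf - gb_rr[i]) * fr;
        } else {
          gb_rr[i] *= f_gb_r0;
        }
        gb_s[i] = gb_s[i] * f_gb_s + gb_rr[i] * (GB_K3 / GB_K4) * (1.0 - f_gb_s);
        double s4 = gb_s[i] * gb_s[i]; s4 *= s4;
        gb = mult_gabab[i] * gGB[i] * s4 / (s4 + GB_KD);
      }

      // conductance balance (all terms ohmic) -> exponential Euler on V
      double gna = par(i, P_GNA) * m[i] * m[i] * m[i] * h[i];
      double gk = par(i, P_GK) * n[i] * n[i] * n[i] * n[i];
      double gm_ = gM * p[i];
      double gh_ = par(i, P_GH) * hH[i];
      double gcan_ = gCAN[i] * mCAN[i];
      double gnap_ = 0.0;
      if (par(i, P_GNAP) > 0) {
        T_nap.look(v, xi, xf);
        gnap_ = par(i, P_GNAP) * xi;
      }
      double eK = par(i, P_EK), eNa = par(i, P_ENA), eCl = par(i, P_ECL);

      double Gsum = gna + gk + gm_ + gt_eff + gh_ + gcan_ + gnap_ +
                    par(i, P_GLEAK) + gKL[i] + gEGA[i] +
                    gampa + ggabaa + gb;
      double GE = gna * eNa + gk * eK + gm_ * eK + gt_eff * par(i, P_ECA) +
                  gh_ * par(i, P_EH) + gcan_ * par(i, P_ECAN) + gnap_ * eNa +
                  par(i, P_GLEAK) * par(i, P_ELEAK) + gKL[i] * eK +
                  gEGA[i] * eCl + gampa * 0.0 + ggabaa * eCl + gb * eK;
      double C = par(i, P_C);
      double vinf = (GE + inj_now) / Gsum;
      double vnew = vinf + (v - vinf) * fexp_neg(dt * Gsum / C);

      // EEG proxy: synaptic currents onto cortical excitatory cells
      if (is_cortical_exc[i]) {
        eeg_step += -(gampa * (v - 0.0) + ggabaa * (v - eCl) + gb * (v - eK));
      }

      // spike detection + event fan-out
      if (v < 0.0 && vnew >= 0.0 && (t - lastspk[i]) >= 2.0) {
        lastspk[i] = t;
        spk_id.push_back(i);
        spk_t.push_back(t + dt);
        for (int k = conn_ptr[i]; k < conn_ptr[i + 1]; ++k) {
          int rec = conn_rec[k];
          int slot = (step + conn_dsteps[k]) % ring_len;
          if (rec == 2) { // GABA-B: transmitter pulse on, then off
            EventSlot on = { conn_tgt[k], 2, conn_w[k] };
            ring[slot].push_back(on);
            EventSlot off = { conn_tgt[k], 3, conn_w[k] };
            ring[(step + conn_dsteps[k] + tdur_steps) % ring_len].push_back(off);
          } else {
            EventSlot ev = { conn_tgt[k], rec, conn_w[k] };
            ring[slot].push_back(ev);
          }
        }
      }
      V[i] = vnew;

      // synaptic gate decay
      ga_r[i] *= f_ar; ga_d[i] *= f_ad;
      gg_r[i] *= f_gr; gg_d[i] *= f_gd;
    }

    eeg_acc += eeg_step;
    if ((step + 1) % eeg_stride == 0) {
      int b = (step + 1) / eeg_stride - 1;
      if (b < n_eeg) {
        eeg[b] = eeg_acc / eeg_stride;
        for (int q = 0; q < nrec; ++q) vrec(b, q) = V[record_ids[q]];
      }
      eeg_acc = 0.0;
    }

    if ((step % check_every) == 0) {
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(V[i]))
          stop("integration failure: non-finite membrane potential (neuron %d, t = %.2f ms)",
               i + 1, t);
      }
    }
  }

  return List::create(
    _["spike_id"] = wrap(spk_id),
    _["spike_t"] = wrap(spk_t),
    _["eeg"] = eeg,
    _["voltages"] = vrec
  );
}

// ---------------------------------------------------------------------------
// Small exported helpers so R-level code and tests share one set of kinetics.
// ---------------------------------------------------------------------------

static bool lookup_rate(const std::string &current, const std::string &var,
                        double v, double &inf, double &tau) {
  if (current == "I_Na" && var == "m") { na_m(v, inf, tau); return true; }
  if (current == "I_Na" && var == "h") { na_h(v, inf, tau); return true; }
  if (current == "I_K" && var == "n") { k_n(v, inf, tau); return true; }
  if (current == "I_M" && var == "p") { m_p(v, inf, tau); return true; }
  if (current == "I_T" && var == "m") { tc_tm(v, inf, tau); return true; }
  if (current == "I_T" && var == "h") { tc_th(v, inf, tau); return true; }
  if (current == "I_T_NRT" && var == "m") { nrt_tm(v, inf, tau); return true; }
  if (current == "I_T_NRT" && var == "h") { nrt_th(v, inf, tau); return true; }
  if (current == "I_h" && var == "h") { h_h(v, inf, tau); return true; }
  if (current == "I_NaP" && var == "m") { nap_m(v, inf, tau); return true; }
  return false;
}

// [[Rcpp::export(name = ".gating_rate")]]
NumericVector gating_rate(std::string current, std::string variable, NumericVector V) {
  NumericVector out(2 * V.size());
  for (int i = 0; i < V.size(); ++i) {
    double inf, tau;
    if (!lookup_rate(current, variable, V[i], inf, tau))
      stop("unknown (current, variable) pair '%s'/'%s'; registered pairs: "
           "I_Na/m, I_Na/h, I_K/n, I_M/p, I_T/m, I_T/h, I_T_NRT/m, I_T_NRT/h, "
           "I_h/h, I_NaP/m", current.c_str(), variable.c_str());
    out[2 * i] = inf; out[2 * i + 1] = tau;
  }
  return out;
}
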