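// Fixed-timestep network integrator.
//
// Each cell is a small tree of cylindrical compartments; the voltage
// step is implicit (backward Euler) along each tree via Hines-ordered
// Gaussian elimination, which is unconditionally stable for the linear
// part.  Channel gates use exact exponential (Rush-Larsen) updates with
// voltage-dependent rates taken from lookup tables built per run;
// synaptic gating uses the exact exponential update of the first-order
// kinetics with the presynaptic drive held constant over the step.
//
// Units: mV, ms, nA, uS, nF (so C dV/dt [nF*mV/ms] = nA and g*V [uS*mV]
// = nA are commensurate).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- Transient Na+ / delayed-rectifier K+ rate functions (Traub-style)
static inline double rate_am(double v) {
  double x = v + 54.0;
  return 0.32 * (std::fabs(x) < 1e-6 ? 4.0 : x / (1.0 - std::exp(-x / 4.0)));
}
static inline double rate_bm(double v) {
  double x = v + 27.0;
  return 0.28 * (std::fabs(x) < 1e-6 ? 5.0 : x / (std::exp(x / 5.0) - 1.0));
}
static inline double rate_ah(double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); }
static inline double rate_bh(double v) { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); }
// delayed rectifier shifted 10 mV depolarized relative to the Na gates,
// so it stays closed over the subthreshold-oscillation voltage range
static inline double rate_an(double v) {
  double x = v + 42.0;
  return 0.032 * (std::fabs(x) < 1e-6 ? 5.0 : x / (1.0 - std::exp(-x / 5.0)));
}
static inline double rate_bn(double v) { return 0.5 * std::exp(-(v + 47.0) / 40.0); }

struct Table {
  // voltage-indexed lookup, linear interpolation
  double vmin, inv_dv;
  int n;
  std::vector<double> y;
  void init(double vmin_, double vmax_, double dv) {
    vmin = vmin_;
    inv_dv = 1.0 / dv;
    n = (int)std::floor((vmax_ - vmin_) / dv) + 1;
    y.assign(n, 0.0);
  }
  inline double at(double v) const {
    double x = (v - vmin) * inv_dv;
    if (x <= 0.0) return y[0];
    if (x >= n - 1) return y[n - 1];
    int i = (int)x;
    double f = x - i;
    return y[i] + f * (y[i + 1] - y[i]);
  }
};

static inline double sigmoid(double v, double theta, double sigma) {
  return 1.0 / (1.0 + std::exp(-(v - theta) / sigma));
}

// [[Rcpp::export]]
List ob_engine_run(List st) {
  const IntegerVector parent = st["parent"];      // 0-based, -1 = root
  const NumericVector g_ax = st["g_ax"];          // uS to parent
  const NumericVector cm = st["cm"];              // nF
  const NumericVector gna = st["gna"], gkdr = st["gkdr"], gl = st["gl"],
                      gnap = st["gnap"], gks = st["gks"], gcat = st["gcat"],
                      gadp = st["gadp"], el = st["el"], tau_ks = st["tau_ks"],
                      tau_adp = st["tau_adp"];
  const double ena = st["ena"], ek = st["ek"], ecat = st["ecat"],
               eadp = st["eadp"];
  const double nap_theta = st["nap_theta"], nap_sigma = st["nap_sigma"];
  const double ks_theta = st["ks_theta"], ks_sigma = st["ks_sigma"];
  const double adp_theta = st["adp_theta"], adp_sigma = st["adp_sigma"];

  const IntegerVector soma_comp = st["soma_comp"]; // per cell, 0-based

  const IntegerVector syn_pre = st["syn_pre"], syn_post = st["syn_post"],
                      syn_kind = st["syn_kind"];   // 0 AMPA, 1 NMDA, 2 GABA_A
  const NumericVector syn_g = st["syn_g"], syn_e = st["syn_e"],
                      syn_alpha = st["syn_alpha"], syn_beta = st["syn_beta"];
  const IntegerVector gaba_col = st["gaba_col"];   // -1 or 0-based column
  const int n_gaba_cols = st["n_gaba_cols"];
  const double mg_mm = st["mg_mm"];

  const NumericVector bg_t = st["bg_t"];
  const IntegerVector bg_comp = st["bg_comp"];
  const NumericVector bg_g = st["bg_g"];   // per-event conductance jump, uS
  const double bg_tau = st["bg_tau"];

  const IntegerVector osn_comp = st["osn_comp"];
  const NumericVector osn_u0 = st["osn_u0"], osn_us = st["osn_us"],
                      osn_gain = st["osn_gain"];
  const double osn_r = st["osn_r"], osn_torn = st["osn_torn"];

  const IntegerVector ic_comp = st["ic_comp"];
  const NumericVector ic_amp = st["ic_amp"], ic_start = st["ic_start"],
                      ic_stop = st["ic_stop"];

  const double dt = st["dt"], t_total = st["t_total"], sample_ms = st["sample_ms"];
  const IntegerVector rec_comp = st["rec_comp"];
  const double spike_thresh = st["spike_thresh"], refract = st["refract"];

  const int ncomp = parent.size();
  const int ncell = soma_comp.size();
  const int nsyn = syn_pre.size();
  const int nsteps = (int)std::lround(t_total / dt);
  const int sample_every = std::max(1, (int)std::lround(sample_ms / dt));
  const int nsamp = nsteps / sample_every + 1;
  const int nrec = rec_comp.size();

  // ---- rate / sigmoid lookup tables for this run's dt
  const double vmin = -130.0, vmax = 70.0, dv = 0.05;
  Table t_minf, t_mfac, t_hinf, t_hfac, t_ninf, t_nfac;
  Table t_ksinf, t_napinf, t_adpinf, t_fexc, t_fgaba, t_bnmda;
  Table* all[] = {&t_minf, &t_mfac, &t_hinf, &t_hfac, &t_ninf, &t_nfac,
                  &t_ksinf, &t_napinf, &t_adpinf, &t_fexc, &t_fgaba,
                  &t_bnmda};
  for (Table* tb : all) tb->init(vmin, vmax, dv);
  for (int i = 0; i < t_minf.n; ++i) {
    double v = vmin + i * dv;
    double am = rate_am(v), bm = rate_bm(v);
    double ah = rate_ah(v), bh = rate_bh(v);
    double an = rate_an(v), bn = rate_bn(v);
    t_minf.y[i] = am / (am + bm); t_mfac.y[i] = std::exp(-dt * (am + bm));
    t_hinf.y[i] = ah / (ah + bh); t_hfac.y[i] = std::exp(-dt * (ah + bh));
    t_ninf.y[i] = an / (an + bn); t_nfac.y[i] = std::exp(-dt * (an + bn));
    t_ksinf.y[i] = sigmoid(v, ks_theta, ks_sigma);
    t_napinf.y[i] = sigmoid(v, nap_theta, nap_sigma);
    t_adpinf.y[i] = sigmoid(v, adp_theta, adp_sigma);
    t_fexc.y[i] = sigmoid(v, 0.0, 0.2);
    t_fgaba.y[i] = sigmoid(v, -40.0, 2.0);
    t_bnmda.y[i] = 1.0 / (1.0 + mg_mm * std::exp(-0.062 * v) / 3.57);
  }

  // ---- state
  std::vector<double> V(ncomp), gm(ncomp), gh(ncomp), gn(ncomp), gw(ncomp),
      gz(ncomp);
  std::vector<double> wfac(ncomp), zfac(ncomp), gbg(ncomp, 0.0);
  for (int i = 0; i < ncomp; ++i) {
    double v = el[i];
    V[i] = v;
    gm[i] = t_minf.at(v); gh[i] = t_hinf.at(v); gn[i] = t_ninf.at(v);
    gw[i] = t_ksinf.at(v);
    gz[i] = t_adpinf.at(v);
    wfac[i] = 1.0 - std::exp(-dt / (tau_ks[i] > 0 ? tau_ks[i] : 10.0));
    zfac[i] = 1.0 - std::exp(-dt / (tau_adp[i] > 0 ? tau_adp[i] : 100.0));
  }
  std::vector<double> s(nsyn, 0.0);
  const double bgfac = std::exp(-dt / bg_tau);

  std::vector<double> diag(ncomp), rhs(ncomp);
  std::vector<double> vprev_soma(ncell), last_spike(ncell, -1e9);
  for (int c = 0; c < ncell; ++c) vprev_soma[c] = V[soma_comp[c]];

  std::vector<double> spike_t;
  std::vector<int> spike_cell;
  spike_t.reserve(4096); spike_cell.reserve(4096);

  NumericMatrix vout(nsamp, nrec);
  NumericMatrix gabaout(n_gaba_cols > 0 ? nsamp : 0, n_gaba_cols);
  NumericVector tout(nsamp);
  int isamp = 0;

  int bg_idx = 0;
  const int nbg = bg_t.size();
  const int nosn = osn_comp.size();
  const int nic = ic_comp.size();

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;

    // ---- sample current state
    if (step % sample_every == 0 && isamp < nsamp) {
      for (int r = 0; r < nrec; ++r) vout(isamp, r) = V[rec_comp[r]];
      if (n_gaba_cols > 0) {
        for (int j = 0; j < nsyn; ++j) {
          int col = gaba_col[j];
          if (col >= 0) gabaout(isamp, col) += syn_g[j] * s[j] * 1000.0; // nS
        }
      }
      tout[isamp] = t;
      ++isamp;
    }
    if (step == nsteps) break;

    // ---- synaptic gating + accumulate conductance loads
    std::fill(diag.begin(), diag.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    for (int j = 0; j < nsyn; ++j) {
      double vpre = V[syn_pre[j]];
      double F = (syn_kind[j] == 2) ? t_fgaba.at(vpre) : t_fexc.at(vpre);
      double aF = syn_alpha[j] * F;
      double a = aF + syn_beta[j];
      double x = dt * a;
      // 1 - exp(-x); series for the small steps the engine takes
      // (error < 1e-8 for x < 0.05), libm otherwise
      double em = (x < 0.05)
        ? x * (1.0 - x * (0.5 - x * (1.0 / 6.0 - x * (1.0 / 24.0))))
        : 1.0 - std::exp(-x);
      s[j] += (aF / a - s[j]) * em;
      double geff = syn_g[j] * s[j];
      if (syn_kind[j] == 1) geff *= t_bnmda.at(V[syn_post[j]]);
      diag[syn_post[j]] += geff;
      rhs[syn_post[j]] += geff * syn_e[j];
    }

    // ---- background conductance (AMPA-kinetics, E = 0 mV)
    for (int i = 0; i < ncomp; ++i) gbg[i] *= bgfac;
    while (bg_idx < nbg && bg_t[bg_idx] <= t) {
      gbg[bg_comp[bg_idx]] += bg_g[bg_idx];
      ++bg_idx;
    }

    // ---- afferent currents
    if (nosn > 0) {
      double shape = 0.5 * (std::tanh(3.0 * (t - osn_torn) / osn_r - 3.0) + 1.0);
      for (int k = 0; k < nosn; ++k) {
        rhs[osn_comp[k]] += osn_gain[k] *
          (osn_u0[k] + (osn_us[k] - osn_u0[k]) * shape);
      }
    }
    for (int k = 0; k < nic; ++k) {
      if (t >= ic_start[k] && t < ic_stop[k]) rhs[ic_comp[k]] += ic_amp[k];
    }

    // ---- gates (exponential updates) and membrane assembly
    const double tab_vmin = t_minf.vmin, tab_invdv = t_minf.inv_dv;
    const int tab_n = t_minf.n;
    for (int i = 0; i < ncomp; ++i) {
      double v = V[i];
      // shared table index for all voltage-dependent terms of this comp
      double x = (v - tab_vmin) * tab_invdv;
      if (x < 0.0) x = 0.0;
      if (x > tab_n - 1.001) x = tab_n - 1.001;
      int ti = (int)x;
      double tf = x - ti;
      #define LERP(tb) (tb.y[ti] + tf * (tb.y[ti + 1] - tb.y[ti]))
      if (gna[i] > 0.0) {
        double minf = LERP(t_minf), mfac = LERP(t_mfac);
        double hinf = LERP(t_hinf), hfac = LERP(t_hfac);
        gm[i] = minf + (gm[i] - minf) * mfac;
        gh[i] = hinf + (gh[i] - hinf) * hfac;
      }
      if (gkdr[i] > 0.0) {
        double ninf = LERP(t_ninf), nfac = LERP(t_nfac);
        gn[i] = ninf + (gn[i] - ninf) * nfac;
      }
      if (gks[i] > 0.0)
        gw[i] += (LERP(t_ksinf) - gw[i]) * wfac[i];
      if (gadp[i] > 0.0)
        gz[i] += (LERP(t_adpinf) - gz[i]) * zfac[i];

      double m2 = gm[i] * gm[i];
      double gna_eff = gna[i] * m2 * gm[i] * gh[i];
      double n2 = gn[i] * gn[i];
      double gk_eff = gkdr[i] * n2 * n2;
      double gks_eff = gks[i] * gw[i];
      double gadp_eff = gadp[i] * gz[i];
      double gnap_eff = gnap[i] > 0.0 ? gnap[i] * LERP(t_napinf) : 0.0;
      #undef LERP

      double c_dt = cm[i] / dt;
      diag[i] += c_dt + gna_eff + gk_eff + gks_eff + gadp_eff + gnap_eff +
                 gl[i] + gcat[i] + gbg[i];
      rhs[i] += c_dt * v + (gna_eff + gnap_eff) * ena +
                (gk_eff + gks_eff) * ek + gadp_eff * eadp +
                gl[i] * el[i] + gcat[i] * ecat;
      // background reversal is 0 mV: no rhs term
    }

    // ---- implicit tree solve (Hines ordering: parent index < child)
    for (int i = ncomp - 1; i >= 0; --i) {
      int p = parent[i];
      if (p >= 0) {
        diag[i] += g_ax[i];
        diag[p] += g_ax[i];
      }
    }
    for (int i = ncomp - 1; i > 0; --i) {
      int p = parent[i];
      if (p >= 0) {
        double f = g_ax[i] / diag[i];
        diag[p] -= f * g_ax[i];
        rhs[p] += f * rhs[i];
      }
    }
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      V[i] = (p < 0) ? rhs[i] / diag[i]
                     : (rhs[i] + g_ax[i] * V[p]) / diag[i];
    }

    // ---- spike detection (somatic upward crossing, refractory lockout)
    for (int c = 0; c < ncell; ++c) {
      double v = V[soma_comp[c]];
      if (v >= spike_thresh && vprev_soma[c] < spike_thresh &&
          (t + dt) - last_spike[c] >= refract) {
        spike_t.push_back(t + dt);
        spike_cell.push_back(c + 1);
        last_spike[c] = t + dt;
      }
      vprev_soma[c] = v;
    }

    // ---- divergence guard
    if ((step & 0x3f) == 0) {
      for (int i = 0; i < ncomp; ++i) {
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0) {
          stop("numerical divergence: |V| > 200 mV in compartment %d at t = %.3f ms",
               i + 1, t);
        }
      }
    }
  }

  return List::create(
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_cell"] = IntegerVector(spike_cell.begin(), spike_cell.end()),
    _["v"] = vout,
    _["gaba"] = gabaout,
    _["t"] = tout);
}
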