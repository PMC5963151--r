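// Human ventricular membrane kinetics (ten Tusscher-Noble-Noble-Panfilov
// 2004 formulation), forward-Euler / Rush-Larsen stepping, fixed-rate
// pacing, and a 1D monodomain cable built on the same cell kernel.
//
// Units: mV, ms, mM, pA/pF. State layout (17):
//   0 V, 1 m, 2 h, 3 j, 4 xr1, 5 xr2, 6 xs, 7 r, 8 s, 9 d, 10 f,
//   11 fCa, 12 g, 13 Cai, 14 CaSR, 15 Nai, 16 Ki
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace tnnp {

const int NSTATE = 17;

// physical constants
const double Rgas = 8314.472, Frd = 96485.3415, Tmp = 310.0;
const double RTONF = Rgas * Tmp / Frd;

// geometry / capacitance
const double CAP = 0.185;            // uF
const double Vc = 0.016404, Vsr = 0.001094;  // uL

// extracellular concentrations (mM)
const double Ko = 5.4, Cao = 2.0, Nao = 140.0;

// buffering
const double Bufc = 0.15, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;

// SR fluxes
const double Vmaxup = 0.000425, Kup = 0.00025;
const double Arel = 0.016464, Brel = 0.25, Crel = 0.008232, Vleak = 8e-5;

// maximal conductances / scaling factors
const double GNa = 14.838, GbNa = 0.00029, GCaL = 0.000175,
             GbCa = 0.000592, GK1 = 5.405, GKr = 0.096, GpK = 0.0146,
             GpCa = 0.825, KpCa = 0.0005, knak = 1.362, KmK = 1.0,
             KmNa = 40.0, knaca = 1000.0, KmNai = 87.5, KmCa = 1.38,
             ksat = 0.1, ncx_gamma = 0.35, pKNa = 0.03;

inline double gto_for(int type)  { return type == 1 ? 0.073 : 0.294; }
inline double gks_for(int type)  { return type == 2 ? 0.062 : 0.245; }

struct Currents {
  double ina, ik1, ito, ikr, iks, ical, inaca, inak, ipca, ipk, ibca, ibna;
  double iion;
};

struct Rates {
  // steady states and time constants for the 12 gates
  double minf, taum, hinf, tauh, jinf, tauj;
  double xr1inf, tauxr1, xr2inf, tauxr2, xsinf, tauxs;
  double rinf, taur, sinf, taus, dinf, taud, finf, tauf;
  double fcainf, taufca, ginf, taug;
};

inline Currents compute_currents(const double* s, int type) {
  const double V = s[0], m = s[1], h = s[2], j = s[3], xr1 = s[4],
               xr2 = s[5], xs = s[6], r = s[7], sg = s[8], d = s[9],
               f = s[10], fca = s[11], Cai = s[13], Nai = s[15],
               Ki = s[16];
  const double EK = RTONF * std::log(Ko / Ki);
  const double ENa = RTONF * std::log(Nao / Nai);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTONF * std::log(Cao / Cai);

  Currents c;
  c.ina = GNa * m * m * m * h * j * (V - ENa);

  double ak1 = 0.1 / (1. + std::exp(0.06 * (V - EK - 200.)));
  double bk1 = (3. * std::exp(0.0002 * (V - EK + 100.)) +
                std::exp(0.1 * (V - EK - 10.))) /
               (1. + std::exp(-0.5 * (V - EK)));
  c.ik1 = GK1 * std::sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - EK);

  c.ito = gto_for(type) * r * sg * (V - EK);
  c.ikr = GKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  c.iks = gks_for(type) * xs * xs * (V - EKs);

  double z = 2.0 * V / RTONF;  // 2VF/RT
  double drv;                  // driving term V*F*(Cai e^z - 0.341 Cao)/(e^z-1)
  if (std::fabs(z) < 1e-5) {
    drv = (RTONF / 2.0) * (Cai * (1.0 + z) - 0.341 * Cao) / (1.0 + z / 2.0);
  } else {
    drv = V * (Cai * std::exp(z) - 0.341 * Cao) / (std::exp(z) - 1.0);
  }
  c.ical = GCaL * d * f * fca * 4.0 * (Frd / RTONF) * drv;

  c.inaca = knaca *
            (std::exp(ncx_gamma * V / RTONF) * Nai * Nai * Nai * Cao -
             std::exp((ncx_gamma - 1.) * V / RTONF) * Nao * Nao * Nao * Cai *
                 2.5) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1. + ksat * std::exp((ncx_gamma - 1.) * V / RTONF)));

  c.inak = knak * Ko * Nai /
           ((Ko + KmK) * (Nai + KmNa) *
            (1. + 0.1245 * std::exp(-0.1 * V / RTONF) +
             0.0353 * std::exp(-V / RTONF)));

  c.ipca = GpCa * Cai / (KpCa + Cai);
  c.ipk = GpK * (V - EK) / (1. + std::exp((25. - V) / 5.98));
  c.ibna = GbNa * (V - ENa);
  c.ibca = GbCa * (V - ECa);

  c.iion = c.ina + c.ik1 + c.ito + c.ikr + c.iks + c.ical + c.inaca +
           c.inak + c.ipca + c.ipk + c.ibca + c.ibna;
  return c;
}

inline Rates compute_rates(const double* s, int type) {
  const double V = s[0], Cai = s[13];
  Rates r;

  r.minf = 1. / std::pow(1. + std::exp((-56.86 - V) / 9.03), 2.0);
  double am = 1. / (1. + std::exp((-60. - V) / 5.));
  double bm = 0.1 / (1. + std::exp((V + 35.) / 5.)) +
              0.1 / (1. + std::exp((V - 50.) / 200.));
  r.taum = am * bm;

  r.hinf = 1. / std::pow(1. + std::exp((V + 71.55) / 7.43), 2.0);
  double ah, bh;
  if (V >= -40.) {
    ah = 0.;
    bh = 0.77 / (0.13 * (1. + std::exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  r.tauh = 1. / (ah + bh);

  r.jinf = r.hinf;
  double aj, bj;
  if (V >= -40.) {
    aj = 0.;
    bj = 0.6 * std::exp(0.057 * V) / (1. + std::exp(-0.1 * (V + 32.)));
  } else {
    aj = (-2.5428e4 * std::exp(0.2444 * V) -
          6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1. + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1. + std::exp(-0.1378 * (V + 40.14)));
  }
  r.tauj = 1. / (aj + bj);

  r.xr1inf = 1. / (1. + std::exp((-26. - V) / 7.));
  double axr1 = 450. / (1. + std::exp((-45. - V) / 10.));
  double bxr1 = 6. / (1. + std::exp((V + 30.) / 11.5));
  r.tauxr1 = axr1 * bxr1;

  r.xr2inf = 1. / (1. + std::exp((V + 88.) / 24.));
  double axr2 = 3. / (1. + std::exp((-60. - V) / 20.));
  double bxr2 = 1.12 / (1. + std::exp((V - 60.) / 20.));
  r.tauxr2 = axr2 * bxr2;

  r.xsinf = 1. / (1. + std::exp((-5. - V) / 14.));
  double axs = 1100. / std::sqrt(1. + std::exp((-10. - V) / 6.));
  double bxs = 1. / (1. + std::exp((V - 60.) / 20.));
  r.tauxs = axs * bxs;

  if (type == 1) {  // endo
    r.rinf = 1. / (1. + std::exp((20. - V) / 6.));
    r.taur = 9.5 * std::exp(-(V + 40.) * (V + 40.) / 1800.) + 0.8;
    r.sinf = 1. / (1. + std::exp((V + 28.) / 5.));
    r.taus = 1000. * std::exp(-(V + 67.) * (V + 67.) / 1000.) + 8.;
  } else {          // epi and mid
    r.rinf = 1. / (1. + std::exp((20. - V) / 6.));
    r.taur = 9.5 * std::exp(-(V + 40.) * (V + 40.) / 1800.) + 0.8;
    r.sinf = 1. / (1. + std::exp((V + 20.) / 5.));
    r.taus = 85. * std::exp(-(V + 45.) * (V + 45.) / 320.) +
             5. / (1. + std::exp((V - 20.) / 5.)) + 3.;
  }

  r.dinf = 1. / (1. + std::exp((-5. - V) / 7.5));
  double ad = 1.4 / (1. + std::exp((-35. - V) / 13.)) + 0.25;
  double bd = 1.4 / (1. + std::exp((V + 5.) / 5.));
  double gd = 1. / (1. + std::exp((50. - V) / 20.));
  r.taud = ad * bd + gd;

  r.finf = 1. / (1. + std::exp((V + 20.) / 7.));
  r.tauf = 1125. * std::exp(-(V + 27.) * (V + 27.) / 240.) + 80. +
           165. / (1. + std::exp((25. - V) / 10.));

  double afca = 1. / (1. + std::pow(Cai / 0.000325, 8.0));
  double bfca = 0.1 / (1. + std::exp((Cai - 0.0005) / 0.0001));
  double gfca = 0.2 / (1. + std::exp((Cai - 0.00075) / 0.0008));
  // the published steady-state expression slightly exceeds 1 at very low
  // calcium; clamp so the gate respects its [0,1] state space
  r.fcainf = std::min(1.0, (afca + bfca + gfca + 0.23) / 1.46);
  r.taufca = 2.;

  r.ginf = (Cai < 0.00035)
               ? 1. / (1. + std::pow(Cai / 0.00035, 6.0))
               : 1. / (1. + std::pow(Cai / 0.00035, 16.0));
  r.taug = 2.;
  return r;
}

inline void gate_update(double& gate, double ginf, double tau, double dt,
                        bool rush) {
  // explicit gate updates are unstable once dt approaches tau (the fast
  // Na activation gate has tau ~ 1e-3 ms at rest), so the exponential
  // (Rush-Larsen) form is used whenever dt is not well inside tau
  if (rush || dt > 0.2 * tau)
    gate = ginf - (ginf - gate) * std::exp(-dt / tau);
  else
    gate += dt * (ginf - gate) / tau;
}

// one forward step of the full cell; i_stim in pA/pF (inward negative),
// extra_dv is an additional voltage rate (mV/ms) e.g. cable diffusion
inline void step_cell(double* s, double dt, double i_stim, int type,
                      bool rush, double extra_dv = 0.0) {
  const Currents c = compute_currents(s, type);
  const Rates rt = compute_rates(s, type);
  const double V = s[0], Cai = s[13], CaSR = s[14];

  // SR fluxes
  double irel = (Arel * CaSR * CaSR / (Brel * Brel + CaSR * CaSR) + Crel) *
                s[9] * s[12];
  double ileak = Vleak * (CaSR - Cai);
  double iup = Vmaxup / (1. + (Kup / Cai) * (Kup / Cai));

  // concentration updates (free-Ca formulation with instantaneous buffers)
  double caifac =
      1. / (1. + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  double dcai = caifac *
                (-(c.ical + c.ibca + c.ipca - 2. * c.inaca) * CAP /
                     (2. * Vc * Frd) +
                 ileak - iup + irel);
  double casrfac =
      1. / (1. + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double dcasr = casrfac * (Vc / Vsr) * (iup - irel - ileak);
  double dnai = -(c.ina + c.ibna + 3. * c.inak + 3. * c.inaca) * CAP /
                (Vc * Frd);
  double dki = -(c.ik1 + c.ito + c.ikr + c.iks - 2. * c.inak + c.ipk +
                 i_stim) *
               CAP / (Vc * Frd);

  // gates
  gate_update(s[1], rt.minf, rt.taum, dt, rush);
  gate_update(s[2], rt.hinf, rt.tauh, dt, rush);
  gate_update(s[3], rt.jinf, rt.tauj, dt, rush);
  gate_update(s[4], rt.xr1inf, rt.tauxr1, dt, rush);
  gate_update(s[5], rt.xr2inf, rt.tauxr2, dt, rush);
  gate_update(s[6], rt.xsinf, rt.tauxs, dt, rush);
  gate_update(s[7], rt.rinf, rt.taur, dt, rush);
  gate_update(s[8], rt.sinf, rt.taus, dt, rush);
  gate_update(s[9], rt.dinf, rt.taud, dt, rush);
  gate_update(s[10], rt.finf, rt.tauf, dt, rush);
  // Ca-dependent inactivation and release gates lock during depolarization
  if (!(rt.fcainf > s[11] && V > -60.))
    gate_update(s[11], rt.fcainf, rt.taufca, dt, rush);
  if (!(rt.ginf > s[12] && V > -60.))
    gate_update(s[12], rt.ginf, rt.taug, dt, rush);

  s[13] += dt * dcai;
  s[14] += dt * dcasr;
  s[15] += dt * dnai;
  s[16] += dt * dki;
  s[0] += dt * (-(c.iion + i_stim) + extra_dv);
}

inline int type_code(const std::string& t) {
  if (t == "epi") return 0;
  if (t == "endo") return 1;
  if (t == "mid") return 2;
  stop("unknown cell type '%s' (use epi, endo or mid)", t.c_str());
  return -1;
}

inline CharacterVector state_names() {
  return CharacterVector::create("v_m", "m", "h", "j", "xr1", "xr2", "xs",
                                 "r", "s", "d", "f", "f_ca", "g", "ca_i",
                                 "ca_sr", "na_i", "k_i");
}

}  // namespace tnnp

// [[Rcpp::export]]
NumericVector tnnp_init_cpp() {
  NumericVector s(tnnp::NSTATE);
  s[0] = -86.2; s[1] = 0.0;  s[2] = 0.75; s[3] = 0.75; s[4] = 0.0;
  s[5] = 1.0;   s[6] = 0.0;  s[7] = 0.0;  s[8] = 1.0;  s[9] = 0.0;
  s[10] = 1.0;  s[11] = 1.0; s[12] = 1.0; s[13] = 0.0002;
  s[14] = 0.2;  s[15] = 11.6; s[16] = 138.3;
  s.attr("names") = tnnp::state_names();
  return s;
}

// [[Rcpp::export]]
NumericVector tnnp_currents_cpp(NumericVector state, std::string cell_type) {
  if (state.size() != tnnp::NSTATE) stop("state must have 17 elements");
  for (int i = 0; i < tnnp::NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state value at position %d",
                                  i + 1);
  tnnp::Currents c = tnnp::compute_currents(REAL(state), //
                                            tnnp::type_code(cell_type));
  NumericVector out = NumericVector::create(
      _["i_na"] = c.ina, _["i_k1"] = c.ik1, _["i_to"] = c.ito,
      _["i_kr"] = c.ikr, _["i_ks"] = c.iks, _["i_cal"] = c.ical,
      _["i_naca"] = c.inaca, _["i_nak"] = c.inak, _["i_pca"] = c.ipca,
      _["i_pk"] = c.ipk, _["i_bca"] = c.ibca, _["i_bna"] = c.ibna,
      _["i_ion"] = c.iion);
  return out;
}

// [[Rcpp::export]]
NumericVector tnnp_step_cpp(NumericVector state, double dt, double i_stim,
                            std::string cell_type, bool rush_larsen) {
  if (state.size() != tnnp::NSTATE) stop("state must have 17 elements");
  if (!R_finite(i_stim)) stop("i_stim must be finite");
  NumericVector s = clone(state);
  tnnp::step_cell(REAL(s), dt, i_stim, tnnp::type_code(cell_type),
                  rush_larsen);
  if (std::fabs(s[0]) > 200.)
    stop("ionic model diverged after 1 step (|V| > 200 mV)");
  s.attr("names") = tnnp::state_names();
  return s;
}

// Pace a single cell for n_beats at fixed cycle length; record v_m and ca_i
// every record_dt ms. Stimulus applied at the start of each cycle.
// [[Rcpp::export]]
List tnnp_pace_cpp(std::string cell_type, double bcl_ms, int n_beats,
                   double dt, double stim_amp, double stim_dur,
                   double record_dt, bool rush_larsen,
                   NumericVector init_state) {
  int type = tnnp::type_code(cell_type);
  std::vector<double> s(tnnp::NSTATE);
  if (init_state.size() == tnnp::NSTATE) {
    for (int i = 0; i < tnnp::NSTATE; ++i) s[i] = init_state[i];
  } else {
    NumericVector s0 = tnnp_init_cpp();
    for (int i = 0; i < tnnp::NSTATE; ++i) s[i] = s0[i];
  }
  long steps_per_beat = (long)std::lround(bcl_ms / dt);
  long rec_every = (long)std::lround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  long total_steps = steps_per_beat * n_beats;
  long n_rec = total_steps / rec_every + 1;
  NumericVector time_ms(n_rec), v_m(n_rec), ca_i(n_rec);
  long k = 0;
  for (long st = 0; st <= total_steps; ++st) {
    if (st % rec_every == 0) {
      time_ms[k] = st * dt;
      v_m[k] = s[0];
      ca_i[k] = s[13];
      ++k;
    }
    if (st == total_steps) break;
    double tb = (st % steps_per_beat) * dt;
    double istim = (tb < stim_dur) ? stim_amp : 0.0;
    tnnp::step_cell(s.data(), dt, istim, type, rush_larsen);
    if (std::fabs(s[0]) > 200.)
      stop("ionic model diverged at step %ld (|V| > 200 mV)", st + 1);
  }
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = tnnp::state_names();
  return List::create(_["time_ms"] = time_ms, _["v_m"] = v_m,
                      _["ca_i_mM"] = ca_i, _["final_state"] = fin);
}

// advance every node of a cable one step: explicit central-difference
// diffusion (no-flux boundaries) plus the reaction term per node.
// states: NSTATE x n_nodes matrix (column = node); stim: per-node pA/pF
// [[Rcpp::export]]
NumericMatrix cable_step_cpp(NumericMatrix states, double dx, double sigma,
                             double beta, double c_m, double dt,
                             NumericVector stim, std::string cell_type,
                             bool rush_larsen) {
  int type = tnnp::type_code(cell_type);
  int n = states.ncol();
  if (states.nrow() != tnnp::NSTATE) stop("states must have 17 rows");
  if (stim.size() != n) stop("stim must have one value per node");
  NumericMatrix S = clone(states);
  double D = sigma / (beta * c_m);
  std::vector<double> lap(n);
  for (int i = 0; i < n; ++i) {
    double vm = S(0, i);
    double vl = (i == 0) ? S(0, 1) : S(0, i - 1);
    double vr = (i == n - 1) ? S(0, n - 2) : S(0, i + 1);
    lap[i] = D * (vl - 2. * vm + vr) / (dx * dx);
  }
  for (int i = 0; i < n; ++i) {
    double col[tnnp::NSTATE];
    for (int k = 0; k < tnnp::NSTATE; ++k) col[k] = S(k, i);
    tnnp::step_cell(col, dt, stim[i], type, rush_larsen, lap[i]);
    for (int k = 0; k < tnnp::NSTATE; ++k) S(k, i) = col[k];
  }
  return S;
}

// 1D monodomain cable: explicit central-difference diffusion with no-flux
// boundaries; reaction from the cell kernel at every node.
// [[Rcpp::export]]
List cable_run_cpp(int n_nodes, double dx, double sigma, double beta,
                   double c_m, double dt, double t_end,
                   IntegerVector stim_nodes, double stim_amp,
                   double stim_start, double stim_dur,
                   std::string cell_type, double record_dt,
                   bool rush_larsen) {
  int type = tnnp::type_code(cell_type);
  if (n_nodes < 3) stop("n_nodes must be >= 3");
  double D = sigma / (beta * c_m);  // cm^2/ms
  NumericVector s0 = tnnp_init_cpp();
  std::vector<std::vector<double>> S(
      n_nodes, std::vector<double>(s0.begin(), s0.end()));
  std::vector<bool> stim(n_nodes, false);
  for (int i = 0; i < stim_nodes.size(); ++i) {
    int ix = stim_nodes[i];
    if (ix < 0 || ix >= n_nodes) stop("stimulus node out of range");
    stim[ix] = true;
  }
  long total_steps = (long)std::lround(t_end / dt);
  long rec_every = (long)std::lround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  long n_rec = total_steps / rec_every + 1;
  NumericMatrix V(n_rec, n_nodes);
  NumericVector time_ms(n_rec);
  std::vector<double> lap(n_nodes);
  long k = 0;
  for (long st = 0; st <= total_steps; ++st) {
    if (st % rec_every == 0) {
      time_ms[k] = st * dt;
      for (int i = 0; i < n_nodes; ++i) V(k, i) = S[i][0];
      ++k;
    }
    if (st == total_steps) break;
    double t = st * dt;
    // no-flux: mirror the neighbour across each boundary
    for (int i = 0; i < n_nodes; ++i) {
      double vm = S[i][0];
      double vl = (i == 0) ? S[1][0] : S[i - 1][0];
      double vr = (i == n_nodes - 1) ? S[n_nodes - 2][0] : S[i + 1][0];
      lap[i] = D * (vl - 2. * vm + vr) / (dx * dx);
    }
    bool stim_on = (t >= stim_start && t < stim_start + stim_dur);
    for (int i = 0; i < n_nodes; ++i) {
      double istim = (stim_on && stim[i]) ? stim_amp : 0.0;
      tnnp::step_cell(S[i].data(), dt, istim, type, rush_larsen, lap[i]);
      if (std::fabs(S[i][0]) > 200.)
        stop("cable diverged at step %ld, node %d (|V| > 200 mV)", st + 1,
             i + 1);
    }
  }
  return List::create(_["time_ms"] = time_ms, _["v_m"] = V);
}
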