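// Cross-bridge myofilament dynamics (Rice-type ODE formulation):
// regulatory units switch between nonpermissive (N) and permissive (P)
// conformations under cooperative troponin-Ca control; permissive units
// attach to a pre-rotation state (XBpreR), rotate to a force-bearing
// post-rotation state (XBpostR) and detach consuming ATP. Mean distortions
// of the attached states carry the force-velocity behaviour. Sarcomere
// length evolves against an elastic load in isotonic mode.
//
// Units: ms, um, uM (calcium), kPa.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace xb {

const int NSTATE = 9;
// 0 n_xb, 1 p_xb, 2 xb_prer, 3 xb_postr, 4 x_prer, 5 x_postr,
// 6 trpn_ca_l, 7 trpn_ca_h, 8 sl

// regulatory / cycling rate constants (per ms; calcium in uM)
const double kon = 0.05, koffL = 0.25, koffH = 0.025;
const double kn_p = 0.5, kp_n = 0.05, perm50 = 0.55, nperm = 15.0;
const double fapp = 0.5, gapp = 0.07, hf = 2.0, hb = 0.4, gxb = 0.07;
const double gslmod = 6.0, hfmdc = 5.0, sigmap = 8.0, sigman = 1.0;
const double x_0 = 0.007;  // um, stroke distance
const double phi = 2.0;    // distortion-kinetics scaling

// sarcomere geometry (um)
const double len_thick = 1.65, len_hbare = 0.1, len_thin = 1.2;
const double sl_min = 1.4, sl_max = 2.4, sl_rest = 1.9, sl_col = 2.25;

// force scaling and passive elements (kPa)
const double kxb = 180.0;
const double pcon_t = 0.002 * kxb, pexp_t = 10.0;
const double pcon_c = 0.02 * kxb, pexp_c = 70.0;
const double visc = 1000.0;  // kPa*ms/um
// ceiling on the strain-modulated cycling rates: during rapid shortening
// the exponential strain factors would otherwise exceed what an explicit
// stepper at dt <= 0.1 ms can integrate; 5/ms is still far faster than any
// twitch timescale
const double rate_cap = 5.0;

inline double clampexp(double x) {
  return std::exp(std::max(-20.0, std::min(20.0, x)));
}

inline double sovf_thick(double sl) {
  double ze = std::min(len_thick / 2., sl / 2.);
  double cle = std::max(sl / 2. - (sl - len_thin), len_hbare / 2.);
  return std::max(0.0, (ze - cle)) * 2. / (len_thick - len_hbare);
}

inline double sovf_thin(double sl) {
  double ze = std::min(len_thick / 2., sl / 2.);
  double cle = std::max(sl / 2. - (sl - len_thin), len_hbare / 2.);
  return std::max(0.0, (ze - cle)) / len_thin;
}

inline double active_tension(const double* s) {
  return kxb * sovf_thick(s[8]) *
         (s[2] * s[4] + s[3] * s[5]) / x_0;
}

inline double passive_tension(double sl) {
  double f = (sl >= sl_rest)
                 ? pcon_t * (clampexp(pexp_t * (sl - sl_rest)) - 1.)
                 : -pcon_t * (clampexp(pexp_t * (sl_rest - sl)) - 1.);
  if (sl > sl_col) f += pcon_c * (clampexp(pexp_c * (sl - sl_col)) - 1.);
  return f;
}

// steady-state duty fractions at reference rates, used to scale the
// mean-distortion kinetics
inline void duty_fractions(double& prer, double& postr) {
  double denom = fapp * hf + gxb * hf + gxb * gapp + hb * fapp +
                 hb * gapp + gxb * fapp;
  prer = (hb * fapp + gxb * fapp) / denom;
  postr = fapp * hf / denom;
}

// one explicit Euler step; mode 0 = isometric (length clamp),
// mode 1 = isotonic against load_kpa. Returns ATP consumption rate
// (detachment flux * overlap, per ms).
inline double step(double* s, double ca, double dt, int mode,
                   double load_kpa) {
  const double sl = s[8];
  const double sthick = sovf_thick(sl), sthin = sovf_thin(sl);

  // troponin calcium binding
  double dL = kon * ca * (1. - s[6]) - koffL * s[6];
  double dH = kon * ca * (1. - s[7]) - koffH * s[7];

  // cooperative permissiveness
  double trop_reg = (1. - sthin) * s[6] + sthin * s[7];
  double permtot =
      std::sqrt(1. / (1. + std::pow(perm50 / std::max(trop_reg, 1e-12),
                                    nperm)));
  double inprmt = std::min(100.0, 1. / permtot);
  double knpT = kn_p * permtot, kpnT = kp_n * inprmt;

  // strain- and overlap-modulated cycling rates
  double gappT = gapp * (1. + (1. - sthick) * gslmod);
  double hfmd = clampexp(-((s[4] >= 0) ? 1.0 : -1.0) * hfmdc *
                         (s[4] / x_0) * (s[4] / x_0));
  double hfT = std::min(hf * hfmd, rate_cap);
  double gxbmd =
      (s[5] < x_0)
          ? clampexp(sigmap * ((x_0 - s[5]) / x_0) * ((x_0 - s[5]) / x_0))
          : clampexp(sigman * ((s[5] - x_0) / x_0) * ((s[5] - x_0) / x_0));
  double gxbT = std::min(gxb * gxbmd, rate_cap);

  double N = s[0], P = s[1], pre = s[2], post = s[3];
  double dN = -knpT * N + kpnT * P;
  double dP = knpT * N - kpnT * P - fapp * P + gappT * pre + gxbT * post;
  double dpre = fapp * P - (gappT + hfT) * pre + hb * post;
  double dpost = hfT * pre - (hb + gxbT) * post;

  // sarcomere-length dynamics
  double dsl = 0.0;
  if (mode == 1) {
    double ft = active_tension(s) + passive_tension(sl);
    dsl = -(ft - load_kpa) / visc;
    if ((sl <= sl_min && dsl < 0) || (sl >= sl_max && dsl > 0)) dsl = 0.0;
  }

  // mean distortions of the attached states
  double dprer_f, dpostr_f;
  duty_fractions(dprer_f, dpostr_f);
  double dxpre = 0.5 * dsl +
                 (phi / dprer_f) *
                     (-fapp * s[4] + hb * (s[5] - x_0 - s[4]));
  double dxpost = 0.5 * dsl + (phi / dpostr_f) * (hf * (s[4] + x_0 - s[5]));

  double atp = gxbT * post * sthick;

  s[0] += dt * dN;
  s[1] += dt * dP;
  s[2] += dt * dpre;
  s[3] += dt * dpost;
  s[4] += dt * dxpre;
  s[5] += dt * dxpost;
  s[6] += dt * dL;
  s[7] += dt * dH;
  s[8] += dt * dsl;
  return atp;
}

inline CharacterVector state_names() {
  return CharacterVector::create("n_xb", "p_xb", "xb_prer", "xb_postr",
                                 "x_prer", "x_postr", "trpn_ca_l",
                                 "trpn_ca_h", "sl");
}

}  // namespace xb

// [[Rcpp::export]]
NumericVector xb_init_cpp(double sl, double ca_dia) {
  if (sl < xb::sl_min || sl > xb::sl_max)
    stop("sarcomere length out of range [%g, %g] um", xb::sl_min,
         xb::sl_max);
  NumericVector s(xb::NSTATE);
  s[0] = 1.0;  // all regulatory units nonpermissive
  s[4] = 0.0;
  s[5] = xb::x_0;
  s[6] = xb::kon * ca_dia / (xb::kon * ca_dia + xb::koffL);
  s[7] = xb::kon * ca_dia / (xb::kon * ca_dia + xb::koffH);
  s[8] = sl;
  s.attr("names") = xb::state_names();
  return s;
}

// [[Rcpp::export]]
double xb_tension_cpp(NumericVector state) {
  if (state.size() != xb::NSTATE) stop("state must have 9 elements");
  return xb::active_tension(REAL(state));
}

// [[Rcpp::export]]
double xb_passive_cpp(double sl) { return xb::passive_tension(sl); }

// [[Rcpp::export]]
NumericVector xb_step_cpp(NumericVector state, double ca_uM, double dt,
                          int mode, double load_kpa) {
  if (state.size() != xb::NSTATE) stop("state must have 9 elements");
  if (ca_uM < 0) stop("ca_uM must be >= 0");
  if (dt > 0.1) stop("dt must be <= 0.1 ms");
  NumericVector s = clone(state);
  xb::step(REAL(s), ca_uM, dt, mode, load_kpa);
  for (int i = 0; i < xb::NSTATE; ++i)
    if (!R_finite(s[i])) stop("non-finite cross-bridge state after step");
  s.attr("names") = xb::state_names();
  return s;
}

// Run the model against a per-step calcium sequence; record every
// rec_every steps. Returns traces and the final state.
// [[Rcpp::export]]
List xb_run_cpp(NumericVector state, NumericVector ca_uM, double dt,
                int mode, double load_kpa, int rec_every) {
  if (state.size() != xb::NSTATE) stop("state must have 9 elements");
  std::vector<double> s(state.begin(), state.end());
  long n = ca_uM.size();
  long n_rec = n / rec_every + 1;
  NumericVector time_ms(n_rec), tension(n_rec), sl(n_rec), atp(n_rec),
      frac_sum(n_rec);
  long k = 0;
  double atp_now = 0.0;
  for (long st = 0; st <= n; ++st) {
    if (st % rec_every == 0 && k < n_rec) {
      time_ms[k] = st * dt;
      tension[k] = xb::active_tension(s.data());
      sl[k] = s[8];
      atp[k] = atp_now;
      frac_sum[k] = s[0] + s[1] + s[2] + s[3];
      ++k;
    }
    if (st == n) break;
    atp_now = xb::step(s.data(), ca_uM[st], dt, mode, load_kpa);
    if (!R_finite(s[0]) || !R_finite(s[8]))
      stop("cross-bridge model produced non-finite values at step %ld",
           st + 1);
  }
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = xb::state_names();
  return List::create(_["time_ms"] = time_ms, _["tension_kpa"] = tension,
                      _["sl_um"] = sl, _["atp_rate"] = atp,
                      _["frac_sum"] = frac_sum, _["final_state"] = fin);
}

// expose the model constants so R-side oracles use identical parameters
// [[Rcpp::export]]
NumericVector xb_params_cpp() {
  return NumericVector::create(
      _["kon"] = xb::kon, _["koffL"] = xb::koffL, _["koffH"] = xb::koffH,
      _["kn_p"] = xb::kn_p, _["kp_n"] = xb::kp_n, _["perm50"] = xb::perm50,
      _["nperm"] = xb::nperm, _["fapp"] = xb::fapp, _["gapp"] = xb::gapp,
      _["hf"] = xb::hf, _["hb"] = xb::hb, _["gxb"] = xb::gxb,
      _["gslmod"] = xb::gslmod, _["x_0"] = xb::x_0, _["kxb"] = xb::kxb,
      _["len_thick"] = xb::len_thick, _["len_hbare"] = xb::len_hbare,
      _["len_thin"] = xb::len_thin, _["sl_rest"] = xb::sl_rest);
}
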