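// Fixed-step closed-loop integrator for the cardiorespiratory exercise
// simulator.  The circulation, lung volume and gas stores are advanced with
// classical RK4 at the hemodynamic step (default 0.25 ms); the autonomic,
// metabolic and ventilation controllers are updated on a coarser control
// step (default 5 ms) on which the delayed efferent activities are buffered.
// All formulas mirror the R reference functions exported by the package.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- parameters

struct Profile {
  std::map<std::string, double> p;
  double operator()(const char *name) const {
    auto it = p.find(name);
    if (it == p.end()) stop("missing profile parameter: %s", name);
    return it->second;
  }
};

static Profile make_profile(const NumericVector &v) {
  Profile pr;
  CharacterVector nm = v.names();
  for (int i = 0; i < v.size(); ++i) pr.p[as<std::string>(nm[i])] = v[i];
  return pr;
}


// circulation constants cached out of the name-keyed profile for the
// inner integration loop
struct CircConst {
  double vla0, vra0, cla, cra, vlv0, vrv0, al, bl, cl, ar, br, cr;
  double rli, rri, rlo, rro, rcp;
  double caa, cabd, cub, ckid, csp, cll, crl, csup, cinfext, cinfint;
  double raa, laa, rabd, labd, rsup, rinfext, rinfint;
  double cap, cvp, vap0, vvp0, rap, lap, rvp;
};

static CircConst make_circ_const(const Profile &P) {
  CircConst c;
  c.vla0 = P("vla0"); c.vra0 = P("vra0"); c.cla = P("cla"); c.cra = P("cra");
  c.vlv0 = P("vlv0"); c.vrv0 = P("vrv0");
  c.al = P("al"); c.bl = P("bl"); c.cl = P("cl");
  c.ar = P("ar"); c.br = P("br"); c.cr = P("cr");
  c.rli = P("rli"); c.rri = P("rri"); c.rlo = P("rlo"); c.rro = P("rro");
  c.rcp = P("rcp");
  c.caa = P("caa"); c.cabd = P("cabd"); c.cub = P("cub"); c.ckid = P("ckid");
  c.csp = P("csp"); c.cll = P("cll"); c.crl = P("crl"); c.csup = P("csup");
  c.cinfext = P("cinfext"); c.cinfint = P("cinfint");
  c.raa = P("raa"); c.laa = P("laa"); c.rabd = P("rabd"); c.labd = P("labd");
  c.rsup = P("rsup"); c.rinfext = P("rinfext"); c.rinfint = P("rinfint");
  c.cap = P("cap"); c.cvp = P("cvp"); c.vap0 = P("vap0"); c.vvp0 = P("vvp0");
  c.rap = P("rap"); c.lap = P("lap"); c.rvp = P("rvp");
  return c;
}

struct GasCurves {
  double n, p50, cap, sol;     // O2 Hill
  double co2_exp, co2_coef;    // CO2 power law
  double k863;
  double o2_content(double p) const {
    double pn = std::pow(p, n), kn = std::pow(p50, n);
    return cap * pn / (kn + pn) + sol * p;
  }
  double o2_slope(double p) const {
    double pn = std::pow(p, n), kn = std::pow(p50, n);
    double s = kn + pn;
    return cap * n * kn * pn / (p * s * s) + sol;
  }
  double co2_content(double p) const { return co2_coef * std::pow(p, co2_exp); }
  double co2_slope(double p) const {
    return co2_coef * co2_exp * std::pow(p, co2_exp - 1.0);
  }
  double co2_pressure(double c) const {
    return std::pow(c / co2_coef, 1.0 / co2_exp);
  }
  // Newton inversion of the O2 curve, warm-started from the previous value
  double o2_pressure(double c, double guess) const {
    double p = std::min(std::max(guess, 1.0), 650.0);
    for (int i = 0; i < 25; ++i) {
      double f = o2_content(p) - c;
      double d = o2_slope(p);
      double step = f / d;
      p -= step;
      if (p < 0.5) p = 0.5;
      if (p > 900.0) p = 900.0;
      if (std::fabs(step) < 1e-10) break;
    }
    return p;
  }
};

// ------------------------------------------------------ circulation network

// state layout (19): 0 vla, 1 vlv, 2 vra, 3 vrv, 4 vaa, 5 vabd, 6 vub,
// 7 vkid, 8 vsp, 9 vll, 10 vrl, 11 vsup, 12 vinfext, 13 vinfint, 14 vap,
// 15 vvp, 16 qaa, 17 qap, 18 t_c
enum {
  VLA, VLV, VRA, VRV, VAA, VABD, VUB, VKID, VSP, VLL, VRL,
  VSUP, VINFEXT, VINFINT, VAP, VVP, QAA, QAP, TC_PHASE, NCIRC
};

// effective (controlled) parameters
struct Eff {
  double tc, elmax, ermax;
  double ruba, rkida, rspa, rlla, rrla;
  double rubv, rkidv, rspv, rllv, rrlv;
  double vub0, vkid0, vsp0, vll0, vrl0;
};

struct CircOut {
  double dy[NCIRC];
  // pressures
  double pla, plv, pra, prv, paa, pabd, pub, pkid, psp, pll, prl,
         psup, pinfext, pinfint, pap, pvp;
  // flows
  double qli, qlo, qub_in, qub_out, qkid_in, qkid_out, qsp_in, qsp_out,
         qll_in, qll_out, qrl_in, qrl_out, qsup, qinf_entry, qinf_ra,
         qri, qro, qvp;
  double paa_elastic;
};

static inline double diode(double pu, double pd, double r) {
  double q = (pu - pd) / r;
  return q > 0.0 ? q : 0.0;
}

static inline double starling(double pin, double pout, double pext, double r) {
  double pd = pout > pext ? pout : pext;
  double q = (pin - pd) / r;
  return q > 0.0 ? q : 0.0;
}

// district elastic pressure: linear above the unstressed volume, steep
// logarithmic collapse branch below it (slope-matched at v0) so external
// compression (muscle pump) cannot squeeze a compartment to non-physical
// negative volume
static inline double compliance_pressure(double v, double v0, double c) {
  if (v >= v0 || v0 <= 0.0) return (v - v0) / c;
  double arg = v / v0;
  if (arg < 1e-6) arg = 1e-6;
  return (v0 / c) * std::log(arg);
}

static void circ_rhs(const double *y, const CircConst &P, const Eff &e,
                     double pintr, double pim_l, double pim_r, CircOut &o) {
  const double tsys = 0.3 * std::sqrt(e.tc);
  double tc_ph = y[TC_PHASE];
  double phi = (tc_ph < tsys) ? std::pow(std::sin(M_PI * tc_ph / tsys), 2) : 0.0;

  o.pla = (y[VLA] - P.vla0) / P.cla + pintr;
  o.pra = (y[VRA] - P.vra0) / P.cra + pintr;
  o.plv = phi * e.elmax * (y[VLV] - P.vlv0) +
          (1 - phi) * (P.al * std::exp(P.bl * y[VLV]) + P.cl) + pintr;
  o.prv = phi * e.ermax * (y[VRV] - P.vrv0) +
          (1 - phi) * (P.ar * std::exp(P.br * y[VRV]) + P.cr) + pintr;

  o.paa_elastic = y[VAA] / P.caa;
  o.paa = o.paa_elastic + pintr;          // ascending aorta: intrathoracic
  o.pabd = y[VABD] / P.cabd;           // descending/abdominal: extrathoracic
  o.pub = compliance_pressure(y[VUB], e.vub0, P.cub);
  o.pkid = compliance_pressure(y[VKID], e.vkid0, P.ckid);
  o.psp = compliance_pressure(y[VSP], e.vsp0, P.csp);
  o.pll = compliance_pressure(y[VLL], e.vll0, P.cll) + pim_l;
  o.prl = compliance_pressure(y[VRL], e.vrl0, P.crl) + pim_r;
  o.psup = y[VSUP] / P.csup + pintr;
  o.pinfext = y[VINFEXT] / P.cinfext;
  o.pinfint = y[VINFINT] / P.cinfint + pintr;
  o.pap = (y[VAP] - P.vap0) / P.cap + pintr;
  o.pvp = (y[VVP] - P.vvp0) / P.cvp + pintr;

  // heart valves (diodes)
  o.qli = diode(o.pla, o.plv, P.rli);
  o.qlo = diode(o.plv, o.paa, P.rlo);
  o.qri = diode(o.pra, o.prv, P.rri);
  o.qro = diode(o.prv, o.pap, P.rro + P.rcp);
  // aortic segments (inertances)
  double qaa = y[QAA], qap = y[QAP];
  // districts
  o.qub_in = (o.paa - o.pub) / e.ruba;
  o.qkid_in = (o.pabd - o.pkid) / e.rkida;
  o.qsp_in = (o.pabd - o.psp) / e.rspa;
  o.qll_in = (o.pabd - o.pll) / e.rlla;
  o.qrl_in = (o.pabd - o.prl) / e.rrla;
  o.qub_out = (o.pub - o.psup) / e.rubv;
  o.qkid_out = (o.pkid - o.pinfext) / e.rkidv;
  o.qsp_out = (o.psp - o.pinfext) / e.rspv;
  o.qll_out = diode(o.pll, o.pinfext, e.rllv);   // leg venous valve
  o.qrl_out = diode(o.prl, o.pinfext, e.rrlv);
  o.qsup = (o.psup - o.pra) / P.rsup;
  o.qinf_entry = starling(o.pinfext, o.pinfint, pintr, P.rinfext);
  o.qinf_ra = (o.pinfint - o.pra) / P.rinfint;
  o.qvp = (o.pvp - o.pla) / P.rvp;

  o.dy[VLA] = o.qvp - o.qli;
  o.dy[VLV] = o.qli - o.qlo;
  o.dy[VAA] = o.qlo - qaa - o.qub_in;
  o.dy[VABD] = qaa - o.qkid_in - o.qsp_in - o.qll_in - o.qrl_in;
  o.dy[VUB] = o.qub_in - o.qub_out;
  o.dy[VKID] = o.qkid_in - o.qkid_out;
  o.dy[VSP] = o.qsp_in - o.qsp_out;
  o.dy[VLL] = o.qll_in - o.qll_out;
  o.dy[VRL] = o.qrl_in - o.qrl_out;
  o.dy[VSUP] = o.qub_out - o.qsup;
  o.dy[VINFEXT] = o.qkid_out + o.qsp_out + o.qll_out + o.qrl_out - o.qinf_entry;
  o.dy[VINFINT] = o.qinf_entry - o.qinf_ra;
  o.dy[VRA] = o.qsup + o.qinf_ra - o.qri;
  o.dy[VRV] = o.qri - o.qro;
  o.dy[VAP] = o.qro - qap;
  o.dy[VVP] = qap - o.qvp;
  o.dy[QAA] = (o.paa - o.pabd - P.raa * qaa) / P.laa;
  o.dy[QAP] = (o.pap - o.pvp - P.rap * qap) / P.lap;
  o.dy[TC_PHASE] = 1.0;
}

// [[Rcpp::export]]
List engine_circulation_derivatives(NumericVector state, NumericVector prof,
                                    NumericVector eff, double pintr,
                                    double pim_left, double pim_right) {
  Profile Pr = make_profile(prof);
  CircConst P = make_circ_const(Pr);
  Eff e;
  e.tc = eff[0]; e.elmax = eff[1]; e.ermax = eff[2];
  e.ruba = eff[3]; e.rkida = eff[4]; e.rspa = eff[5]; e.rlla = eff[6];
  e.rrla = eff[7];
  e.rubv = eff[8]; e.rkidv = eff[9]; e.rspv = eff[10]; e.rllv = eff[11];
  e.rrlv = eff[12];
  e.vub0 = eff[13]; e.vkid0 = eff[14]; e.vsp0 = eff[15]; e.vll0 = eff[16];
  e.vrl0 = eff[17];
  CircOut o;
  std::vector<double> y(state.begin(), state.end());
  circ_rhs(y.data(), P, e, pintr, pim_left, pim_right, o);
  NumericVector dy(NCIRC);
  for (int i = 0; i < NCIRC; ++i) dy[i] = o.dy[i];
  NumericVector pres = NumericVector::create(
    _["pla"] = o.pla, _["plv"] = o.plv, _["pra"] = o.pra, _["prv"] = o.prv,
    _["paa"] = o.paa, _["pabd"] = o.pabd, _["pub"] = o.pub,
    _["pkid"] = o.pkid, _["psp"] = o.psp, _["pll"] = o.pll, _["prl"] = o.prl,
    _["psup"] = o.psup, _["pinfext"] = o.pinfext, _["pinfint"] = o.pinfint,
    _["pap"] = o.pap, _["pvp"] = o.pvp, _["paa_elastic"] = o.paa_elastic);
  NumericVector flows = NumericVector::create(
    _["qli"] = o.qli, _["qlo"] = o.qlo, _["qri"] = o.qri, _["qro"] = o.qro,
    _["qub_in"] = o.qub_in, _["qub_out"] = o.qub_out,
    _["qkid_in"] = o.qkid_in, _["qkid_out"] = o.qkid_out,
    _["qsp_in"] = o.qsp_in, _["qsp_out"] = o.qsp_out,
    _["qll_in"] = o.qll_in, _["qll_out"] = o.qll_out,
    _["qrl_in"] = o.qrl_in, _["qrl_out"] = o.qrl_out,
    _["qsup"] = o.qsup, _["qinf_entry"] = o.qinf_entry,
    _["qinf_ra"] = o.qinf_ra, _["qvp"] = o.qvp);
  return List::create(_["derivatives"] = dy, _["pressures"] = pres,
                      _["flows"] = flows);
}

// ------------------------------------------------------------ coupled model

// full fast-state layout: circulation (19) + v_lungs, po2_alv, pco2_alv,
// v_a, m_o2_mv, m_co2_mv, m_o2_art, m_co2_art, then 5 district O2 contents
// and 5 district CO2 contents (ml/dl)
enum {
  VLUNGS = NCIRC, PO2ALV, PCO2ALV, VA_INC,
  MO2MV, MCO2MV, MO2ART, MCO2ART, CDIST0, NFAST = CDIST0 + 10
};

struct Drive {                 // per-control-step external inputs
  double wl;
  double vo2[5];               // ml/min per district (ub, kid, sp, ll, rl)
  double rq;
  double tv, freq, tveff;      // current breath pattern
  double va_gain;              // dVlungs -> alveolar ventilation scale
  double t_b0;                 // absolute time of current breath start
};

struct FullOut {
  CircOut c;
  double dy[NFAST];
  double pintr, ppl;
  double o2_uptake, co2_output;       // ml STPD/s across the lung
  double c_o2_art, c_o2_mv, c_co2_art, c_co2_mv;  // ml/dl
};

struct Model {
  Profile P;
  CircConst CC;
  GasCurves G;
  double ppl0_gauge, pim_max, k_dv, e_lung, r_airways, ps, po2_i, pco2_i,
         v_eexp;
  double c_ref[5], k_met;

  void rhs(double t, const double *y, const Eff &e, const Drive &d,
           FullOut &o) const {
    // respiratory drive (prescribed pleural sinusoid)
    double tb = t - d.t_b0;
    double amp = e_lung * d.tv / 2.0;
    o.ppl = ppl0_gauge - amp * std::sin(2.0 * M_PI * (d.freq / 60.0) * tb);
    o.pintr = o.ppl;
    double dvlungs = (0.0 - o.ppl - y[VLUNGS] * e_lung) / r_airways;
    o.dy[VLUNGS] = dvlungs;
    // alveolar ventilation: the lung-volume waveform scaled so that one
    // breath delivers exactly the effective (dead-space-corrected) tidal
    // volume to the alveoli (the airway time constant attenuates the
    // delivered excursion of the pleural sinusoid by E/sqrt(E^2+w^2R^2))
    double vdot_a = d.va_gain * dvlungs;      // signed, l/s
    o.dy[VA_INC] = vdot_a;

    // leg muscle pump (1 Hz cycling)
    double pim_l = pim_max * d.wl * (1.0 + std::sin(2.0 * M_PI * t));
    double pim_r = pim_max * d.wl * (1.0 + std::sin(2.0 * M_PI * t + M_PI));

    circ_rhs(y, CC, e, o.pintr, pim_l, pim_r, o.c);

    // blood-gas pools
    double v_art = y[VVP] + y[VLA] + y[VLV] + y[VAA] + y[VABD];
    double v_mv = y[VSUP] + y[VINFEXT] + y[VINFINT] + y[VRA] + y[VRV] + y[VAP];
    double c_o2_art = 100.0 * y[MO2ART] / v_art;     // ml/dl
    double c_co2_art = 100.0 * y[MCO2ART] / v_art;
    double c_o2_mv = 100.0 * y[MO2MV] / v_mv;
    double c_co2_mv = 100.0 * y[MCO2MV] / v_mv;
    o.c_o2_art = c_o2_art; o.c_co2_art = c_co2_art;
    o.c_o2_mv = c_o2_mv; o.c_co2_mv = c_co2_mv;

    // alveolar mass balance (contents handled as ml/ml)
    double qap = y[QAP] > 0.0 ? y[QAP] : 0.0;        // exchange flow cm3/s
    double q_l = qap / 1000.0;
    double vap_l = y[VAP] / 1000.0;
    double c_o2_eq = G.o2_content(y[PO2ALV]) / 100.0;
    double c_co2_eq = G.co2_content(y[PCO2ALV]) / 100.0;
    double v_alv = v_eexp + y[VA_INC];
    if (v_alv < 0.5) v_alv = 0.5;
    double cap_o2 = v_alv + G.k863 * vap_l * G.o2_slope(y[PO2ALV]) / 100.0;
    double cap_co2 = v_alv + G.k863 * vap_l * G.co2_slope(y[PCO2ALV]) / 100.0;
    double perf_o2 = G.k863 * (1 - ps) * q_l * (c_o2_mv / 100.0 - c_o2_eq);
    double perf_co2 = G.k863 * (1 - ps) * q_l * (c_co2_mv / 100.0 - c_co2_eq);
    bool insp = dvlungs > 0.0;
    double fresh_o2 = insp ? (vdot_a * (po2_i - y[PO2ALV])) : 0.0;
    double fresh_co2 = insp ? (vdot_a * (pco2_i - y[PCO2ALV])) : 0.0;
    o.dy[PO2ALV] = (perf_o2 + fresh_o2) / cap_o2;
    o.dy[PCO2ALV] = (perf_co2 + fresh_co2) / cap_co2;
    o.o2_uptake = (1 - ps) * q_l * (c_o2_eq - c_o2_mv / 100.0) * 1000.0;
    o.co2_output = (1 - ps) * q_l * (c_co2_mv / 100.0 - c_co2_eq) * 1000.0;

    // arterial pool: gains shunt-mixed end-capillary blood, loses district
    // arterial outflows (upwind on flow sign)
    double c_in_o2 = (1 - ps) * c_o2_eq * 100.0 + ps * c_o2_mv;   // ml/dl
    double c_in_co2 = (1 - ps) * c_co2_eq * 100.0 + ps * c_co2_mv;
    double dm_o2_art = qap * c_in_o2 / 100.0;
    double dm_co2_art = qap * c_in_co2 / 100.0;
    double dm_o2_mv = -qap * c_o2_mv / 100.0;
    double dm_co2_mv = -qap * c_co2_mv / 100.0;

    const double q_in[5] = { o.c.qub_in, o.c.qkid_in, o.c.qsp_in,
                             o.c.qll_in, o.c.qrl_in };
    const double q_out[5] = { o.c.qub_out, o.c.qkid_out, o.c.qsp_out,
                              o.c.qll_out, o.c.qrl_out };
    const double dv[5] = { o.c.dy[VUB], o.c.dy[VKID], o.c.dy[VSP],
                           o.c.dy[VLL], o.c.dy[VRL] };
    const int vidx[5] = { VUB, VKID, VSP, VLL, VRL };
    for (int i = 0; i < 5; ++i) {
      double ci_o2 = y[CDIST0 + i];
      double ci_co2 = y[CDIST0 + 5 + i];
      if (ci_o2 < 0.0) ci_o2 = 0.0;
      // upwind arterial-side flux
      double f_o2_in, f_co2_in;
      if (q_in[i] >= 0.0) {
        f_o2_in = q_in[i] * c_o2_art / 100.0;
        f_co2_in = q_in[i] * c_co2_art / 100.0;
      } else {
        f_o2_in = q_in[i] * ci_o2 / 100.0;
        f_co2_in = q_in[i] * ci_co2 / 100.0;
      }
      dm_o2_art -= f_o2_in;
      dm_co2_art -= f_co2_in;
      // upwind venous-side flux
      double f_o2_out, f_co2_out;
      if (q_out[i] >= 0.0) {
        f_o2_out = q_out[i] * ci_o2 / 100.0;
        f_co2_out = q_out[i] * ci_co2 / 100.0;
      } else {
        f_o2_out = q_out[i] * c_o2_mv / 100.0;
        f_co2_out = q_out[i] * c_co2_mv / 100.0;
      }
      dm_o2_mv += f_o2_out;
      dm_co2_mv += f_co2_out;
      double vi = y[vidx[i]];
      // supply limitation: extraction cannot exceed the O2 actually present;
      // quadratic roll-off engages only as the venous store approaches zero
      // (half-effect at 0.05 ml/dl, <0.3% above 1 ml/dl)
      double f_lim = ci_o2 * ci_o2 / (ci_o2 * ci_o2 + 0.05 * 0.05);
      double vo2_eff = d.vo2[i] * f_lim;
      double dm_o2 = f_o2_in - f_o2_out - vo2_eff / 60.0;
      double dm_co2 = f_co2_in - f_co2_out + d.rq * vo2_eff / 60.0;
      o.dy[CDIST0 + i] = (dm_o2 - ci_o2 / 100.0 * dv[i]) / vi * 100.0;
      o.dy[CDIST0 + 5 + i] = (dm_co2 - ci_co2 / 100.0 * dv[i]) / vi * 100.0;
    }
    o.dy[MO2ART] = dm_o2_art;
    o.dy[MCO2ART] = dm_co2_art;
    o.dy[MO2MV] = dm_o2_mv;
    o.dy[MCO2MV] = dm_co2_mv;
    for (int i = 0; i < NCIRC; ++i) o.dy[i] = o.c.dy[i];
  }
};

// ----------------------------------------------------------------- controls

struct Controller {
  // baroreflex afferent/efferent
  double p_filt;
  std::vector<double> fes_buf, fev_buf;
  size_t buf_pos_s, buf_pos_v;
  // effector deviations
  double d_tcs, d_tcv, d_elmax, d_ermax;
  double d_ria_s[5], d_vi0_s[5];
  double d_ria_met[5], d_riv_met[5];
  // ventilation controller
  double vent, freq, tv, tveff;
  double acc_po2, acc_pco2; int acc_n;
  double po2_art_prev, pco2_art_prev;
};

// [[Rcpp::export]]
List engine_run(NumericVector state0, NumericVector prof,
                NumericVector gas_const, NumericMatrix stages, List numerics) {
  Model M;
  M.P = make_profile(prof);
  M.CC = make_circ_const(M.P);
  M.G.n = gas_const["o2_n"]; M.G.p50 = gas_const["o2_p50"];
  M.G.cap = gas_const["o2_cap"]; M.G.sol = gas_const["o2_sol"];
  M.G.co2_exp = gas_const["co2_exp"]; M.G.co2_coef = gas_const["co2_coef"];
  M.G.k863 = gas_const["k863"];
  const Profile &P = M.P;
  M.ppl0_gauge = P("ppl0") - 760.0;
  M.pim_max = P("pim_max"); M.k_dv = P("k_dv"); M.e_lung = P("e_lung");
  M.r_airways = P("r_airways"); M.ps = P("ps_shunt");
  M.po2_i = P("po2_i"); M.pco2_i = P("pco2_i"); M.v_eexp = P("v_eexp");
  M.k_met = P("k_met");
  M.c_ref[0] = P("c_o2ubv_ref"); M.c_ref[1] = P("c_o2kidv_ref");
  M.c_ref[2] = P("c_o2spv_ref"); M.c_ref[3] = P("c_o2llv_ref");
  M.c_ref[4] = P("c_o2rlv_ref");

  const double dt = as<double>(numerics["dt"]);
  const double dtc = as<double>(numerics["dt_control"]);
  const double record_dt = as<double>(numerics["record_dt"]);
  const double clamp_paa = numerics.containsElementNamed("clamp_paa") ?
    as<double>(numerics["clamp_paa"]) : NA_REAL;
  const bool clamped = R_finite(clamp_paa);
  const int nsub = (int) std::lround(dtc / dt);
  if (nsub < 1 || std::fabs(nsub * dt - dtc) > 1e-12)
    stop("dt_control must be a multiple of dt");

  // stage table
  const int nstage = stages.nrow();
  std::vector<double> st_start(nstage), st_wl(nstage);
  double t_end = 0;
  for (int i = 0; i < nstage; ++i) {
    st_start[i] = stages(i, 0);
    st_wl[i] = stages(i, 2);
    t_end = stages(i, 0) + stages(i, 1);
  }

  // baroreflex constants
  const double tau_p = P("tau_p"), tau_z = P("tau_z");
  const double ka = P("ka"), fas_min = P("fas_min"), fas_max = P("fas_max");
  const double kes = P("kes"), fes0 = P("fes0"), fes_inf = P("fes_inf");
  const double kev = P("kev"), fev0 = P("fev0"), fev_inf0 = P("fev_inf0");
  const double b_reset = P("b_reset"), c_reset = P("c_reset"),
               d_reset = P("d_reset"), a_reset = P("a_reset"),
               paa_set0 = P("paa_set0");
  const double fas0 = fas_min + fas_max / 2.0;
  const double fes_set = fes_inf + (fes0 - fes_inf) * std::exp(-kes * fas0);
  const double fev_set = (fev0 + fev_inf0) / 2.0;
  const double log_ref = std::log(fes_set - fes_inf + 1.0);
  const double tc_set = 60.0 / P("hr_set");
  // effector gains / time constants (channel order: ub, kid, sp, ll, rl)
  const double c_ria_s[5] = { P("c_rubas"), P("c_rkidas"), P("c_rspas"),
                              P("c_rllas"), P("c_rrlas") };
  const double c_vi0_s[5] = { P("c_vub0s"), P("c_vkid0s"), P("c_vsp0s"),
                              P("c_vll0s"), P("c_vrl0s") };
  const double c_ria_met[5] = { P("c_rubamet"), P("c_rkidamet"),
                                P("c_rspamet"), P("c_rllamet"),
                                P("c_rrlamet") };
  const double c_riv_met[5] = { P("c_rubvmet"), P("c_rkidvmet"),
                                P("c_rspvmet"), P("c_rllvmet"),
                                P("c_rrlvmet") };
  const double ria_set[5] = { P("ruba_set"), P("rkida_set"), P("rspa_set"),
                              P("rlla_set"), P("rrla_set") };
  const double riv_set[5] = { P("rubv_set"), P("rkidv_set"), P("rspv_set"),
                              P("rllv_set"), P("rrlv_set") };
  const double vi0_set[5] = { P("vub0_set"), P("vkid0_set"), P("vsp0_set"),
                              P("vll0_set"), P("vrl0_set") };
  const double s0 = P("s0");
  const double t_ris = P("t_ris"), t_vis = P("t_vis"), t_met = P("t_met"),
               t_elmax = P("t_elmax"), t_ermax = P("t_ermax"),
               t_tcs = P("t_tcs"), t_tcv = P("t_tcv");
  const double split[3] = { P("split_ub"), P("split_kid"), P("split_sp") };

  auto e_upd = [](double x, double target, double dt_, double tau) {
    return target + (x - target) * std::exp(-dt_ / tau);
  };

  // ---------------------------------------------------------------- init
  std::vector<double> y(NFAST, 0.0);
  for (int i = 0; i < NCIRC; ++i) y[i] = state0[i];
  double po2_alv0 = 100.0, pco2_alv0 = 40.0;
  y[PO2ALV] = po2_alv0; y[PCO2ALV] = pco2_alv0; y[VA_INC] = 0.0;
  double c_art_o2_0 = M.G.o2_content(95.0), c_art_co2_0 = M.G.co2_content(40.0);
  double c_mv_o2_0 = 0.0;
  for (int i = 0; i < 5; ++i) c_mv_o2_0 += M.c_ref[i] / 5.0;
  double c_mv_co2_0 = M.G.co2_content(46.0);
  {
    double v_art = y[VVP] + y[VLA] + y[VLV] + y[VAA] + y[VABD];
    double v_mv = y[VSUP] + y[VINFEXT] + y[VINFINT] + y[VRA] + y[VRV] + y[VAP];
    y[MO2ART] = c_art_o2_0 / 100.0 * v_art;
    y[MCO2ART] = c_art_co2_0 / 100.0 * v_art;
    y[MO2MV] = c_mv_o2_0 / 100.0 * v_mv;
    y[MCO2MV] = c_mv_co2_0 / 100.0 * v_mv;
  }
  for (int i = 0; i < 5; ++i) {
    y[CDIST0 + i] = M.c_ref[i];
    y[CDIST0 + 5 + i] = M.G.co2_content(46.0);
  }
  // lung volume at the static equilibrium of the mean pleural pressure
  y[VLUNGS] = -M.ppl0_gauge / M.e_lung;

  Controller C;
  C.p_filt = clamped ? clamp_paa : (y[VAA] / P("caa"));
  int n_hs = (int) std::lround(P("d_hs") / dtc);
  int n_hv = (int) std::lround(P("d_hv") / dtc);
  if (n_hs < 1) n_hs = 1;
  if (n_hv < 1) n_hv = 1;
  C.fes_buf.assign(n_hs, fes_set);
  C.fev_buf.assign(n_hv, fev_set);
  C.buf_pos_s = C.buf_pos_v = 0;
  C.d_tcs = C.d_tcv = C.d_elmax = C.d_ermax = 0.0;
  for (int i = 0; i < 5; ++i) {
    C.d_ria_s[i] = C.d_vi0_s[i] = C.d_ria_met[i] = C.d_riv_met[i] = 0.0;
  }
  C.po2_art_prev = 95.0; C.pco2_art_prev = 40.0;
  C.acc_po2 = C.acc_pco2 = 0.0; C.acc_n = 0;
  C.vent = std::max(0.0, (P("alpha") * std::exp(P("beta") * 95.0) + P("gamma"))
                          * (40.0 - P("pco2_tr")));
  C.freq = P("delta") * C.vent + P("epsilon");
  C.tv = C.vent > 0 ? C.vent / C.freq : 0.0;
  C.tveff = C.tv * M.k_dv;

  auto va_gain_for = [&](double freq) {
    double w = 2.0 * M_PI * freq / 60.0;
    double att = M.e_lung / std::sqrt(M.e_lung * M.e_lung +
                                      w * w * M.r_airways * M.r_airways);
    return M.k_dv / att;
  };

  Drive D;
  D.t_b0 = 0.0;
  D.tv = C.tv; D.freq = C.freq; D.tveff = C.tveff;
  D.va_gain = va_gain_for(C.freq);

  Eff e;
  e.tc = tc_set; e.elmax = P("elmax"); e.ermax = P("ermax");
  e.ruba = ria_set[0]; e.rkida = ria_set[1]; e.rspa = ria_set[2];
  e.rlla = ria_set[3]; e.rrla = ria_set[4];
  e.rubv = riv_set[0]; e.rkidv = riv_set[1]; e.rspv = riv_set[2];
  e.rllv = riv_set[3]; e.rrlv = riv_set[4];
  e.vub0 = vi0_set[0]; e.vkid0 = vi0_set[1]; e.vsp0 = vi0_set[2];
  e.vll0 = vi0_set[3]; e.vrl0 = vi0_set[4];

  double fas = fas0, fes = fes_set, fev = fev_set;

  // cycle and series records
  const int NCYC_COL = 45;
  std::vector<double> cycles;
  const int NSER_COL = 28;
  std::vector<double> series;
  double next_record = 0.0;

  // per-cycle accumulators (trapezoid-free left sums at dt)
  struct CycAcc {
    double t0 = 0.0, n = 0.0;
    double paa = 0, pra = 0, qlo = 0, qll = 0, qrl = 0, qub = 0, qkid = 0,
           qsp = 0, cart_o2 = 0, cmv_o2 = 0, cart_co2 = 0, cmv_co2 = 0,
           vsp = 0, pintr = 0, o2up = 0, co2out = 0, po2alv = 0, pco2alv = 0,
           afas = 0, afes = 0, afev = 0,
           min_valve = 1e30, pintr_min = 1e30;
    void reset(double t) {
      *this = CycAcc(); t0 = t;
    }
  } cyc;
  cyc.t0 = 0.0;

  int neg_volume_events = 0;
  int o2_debt_steps = 0;
  bool nan_abort = false;

  double blood0 = 0.0;
  for (int i = VLA; i <= VVP; ++i) blood0 += y[i];

  const int nctrl = (int) std::lround(t_end / dtc);
  double t = 0.0;
  std::vector<double> k1(NFAST), k2(NFAST), k3(NFAST), k4(NFAST),
                      ytmp(NFAST);
  FullOut o1, o2, o3, o4;

  int stage_idx = 0;

  for (int ic = 0; ic < nctrl && !nan_abort; ++ic) {
    // --------------------------- control update (every dtc)
    // stage / workload
    while (stage_idx + 1 < nstage && t >= st_start[stage_idx + 1] - 1e-9)
      ++stage_idx;
    double wl = clamped && numerics.containsElementNamed("clamp_wl") ?
      as<double>(numerics["clamp_wl"]) : st_wl[stage_idx];
    D.wl = wl;
    double rr = P("vo2_rr_0") + P("vo2_rr_slope") * wl;
    double leg = P("vo2_leg_slope") * wl + P("vo2_leg_0");
    D.vo2[0] = rr * split[0]; D.vo2[1] = rr * split[1];
    D.vo2[2] = rr * split[2]; D.vo2[3] = leg; D.vo2[4] = leg;
    D.rq = P("rq_0") + P("rq_slope") * wl;

    // baroreflex afferent path
    FullOut onow;
    M.rhs(t, y.data(), e, D, onow);
    double paa_el = onow.c.paa_elastic;
    double dpaa_el = onow.c.dy[VAA] / P("caa");
    if (clamped) {
      C.p_filt = clamp_paa;
    } else {
      double target = paa_el + tau_z * dpaa_el;
      C.p_filt = e_upd(C.p_filt, target, dtc, tau_p);
    }
    double paa_set = paa_set0 + a_reset * wl;
    double z = (C.p_filt - paa_set) / ka;
    double sig = 1.0 / (1.0 + std::exp(-z));
    fas = fas_min + fas_max * sig;
    fes = fes_inf + (fes0 - fes_inf) * std::exp(-kes * fas) + b_reset * wl;
    double w = (fas - fas0) / kev;
    double sigv = 1.0 / (1.0 + std::exp(-w));
    double fev_inf = fev_inf0 + d_reset * wl;
    fev = fev0 * (1.0 - sigv) + fev_inf * sigv + c_reset * wl;
    if (fev < 0.0) fev = 0.0;
    // delay lines
    double fes_d = C.fes_buf[C.buf_pos_s];
    C.fes_buf[C.buf_pos_s] = fes;
    C.buf_pos_s = (C.buf_pos_s + 1) % C.fes_buf.size();
    double fev_d = C.fev_buf[C.buf_pos_v];
    C.fev_buf[C.buf_pos_v] = fev;
    C.buf_pos_v = (C.buf_pos_v + 1) % C.fev_buf.size();
    // static responses
    double arg = fes_d - fes_inf + 1.0;
    if (arg < 1e-9) arg = 1e-9;
    double lf = std::log(arg) - log_ref;
    double sf_v = fev_d - fev_set;
    // effector dynamics (exact exponential steps)
    C.d_tcs = e_upd(C.d_tcs, P("c_tcs") * lf, dtc, t_tcs);
    C.d_tcv = e_upd(C.d_tcv, P("c_tcv") * sf_v, dtc, t_tcv);
    C.d_elmax = e_upd(C.d_elmax, P("c_elmaxs") * lf, dtc, t_elmax);
    C.d_ermax = e_upd(C.d_ermax, P("c_ermaxs") * lf, dtc, t_ermax);
    double sf_met[5];
    for (int i = 0; i < 5; ++i) {
      C.d_ria_s[i] = e_upd(C.d_ria_s[i], c_ria_s[i] * lf, dtc, t_ris);
      C.d_vi0_s[i] = e_upd(C.d_vi0_s[i], c_vi0_s[i] * lf, dtc, t_vis);
      double ci = y[CDIST0 + i];
      if (ci < 0.0) ci = 0.0;
      double sm = 1.0 - 1.0 / (1.0 + std::exp(M.k_met * (ci - M.c_ref[i] / 2.0)));
      sf_met[i] = sm;
      C.d_ria_met[i] = e_upd(C.d_ria_met[i], c_ria_met[i] * (sm - 1.0), dtc,
                             t_met);
      C.d_riv_met[i] = e_upd(C.d_riv_met[i], c_riv_met[i] * (sm - 1.0), dtc,
                             t_met);
    }
    // effective parameters
    e.tc = tc_set + C.d_tcs + C.d_tcv;
    if (e.tc < 0.25) e.tc = 0.25;
    e.elmax = P("elmax") + C.d_elmax;
    if (e.elmax < 0.1) e.elmax = 0.1;
    e.ermax = P("ermax") + C.d_ermax;
    if (e.ermax < 0.05) e.ermax = 0.05;
    double ria_eff[5], riv_eff[5], vi0_eff[5];
    for (int i = 0; i < 5; ++i) {
      double g = std::pow(sf_met[i], 10.0);
      double r = ria_set[i] * s0 + (ria_set[i] * (1.0 - s0) + C.d_ria_s[i]) * g
                 + C.d_ria_met[i];
      double floor_r = 0.05 * ria_set[i] * s0;
      ria_eff[i] = r > floor_r ? r : floor_r;
      double rv = riv_set[i] + C.d_riv_met[i];
      double floor_v = 0.05 * riv_set[i];
      riv_eff[i] = rv > floor_v ? rv : floor_v;
      double v0 = vi0_set[i] + C.d_vi0_s[i];
      vi0_eff[i] = v0 > 0.0 ? v0 : 0.0;
    }
    e.ruba = ria_eff[0]; e.rkida = ria_eff[1]; e.rspa = ria_eff[2];
    e.rlla = ria_eff[3]; e.rrla = ria_eff[4];
    e.rubv = riv_eff[0]; e.rkidv = riv_eff[1]; e.rspv = riv_eff[2];
    e.rllv = riv_eff[3]; e.rrlv = riv_eff[4];
    e.vub0 = vi0_eff[0]; e.vkid0 = vi0_eff[1]; e.vsp0 = vi0_eff[2];
    e.vll0 = vi0_eff[3]; e.vrl0 = vi0_eff[4];

    // ventilation controller: accumulate arterial tensions, retune at breath
    // boundaries only
    {
      double v_art = y[VVP] + y[VLA] + y[VLV] + y[VAA] + y[VABD];
      double c_o2 = 100.0 * y[MO2ART] / v_art;
      double c_co2 = 100.0 * y[MCO2ART] / v_art;
      C.po2_art_prev = M.G.o2_pressure(c_o2, C.po2_art_prev);
      C.pco2_art_prev = M.G.co2_pressure(c_co2);
      C.acc_po2 += C.po2_art_prev;
      C.acc_pco2 += C.pco2_art_prev;
      C.acc_n += 1;
      double breath_period = 60.0 / D.freq;
      if (t - D.t_b0 >= breath_period - 1e-9) {
        double po2m = C.acc_po2 / C.acc_n, pco2m = C.acc_pco2 / C.acc_n;
        double drive = (P("alpha") * std::exp(P("beta") * po2m) + P("gamma"))
                       * (pco2m - P("pco2_tr"));
        C.vent = drive > 0.0 ? drive : 0.0;
        C.freq = P("delta") * C.vent + P("epsilon");
        C.tv = C.vent > 0.0 ? C.vent / C.freq : 0.0;
        C.tveff = C.tv * M.k_dv;
        C.acc_po2 = C.acc_pco2 = 0.0; C.acc_n = 0;
        D.t_b0 = t;
        D.tv = C.tv; D.freq = C.freq; D.tveff = C.tveff;
        D.va_gain = va_gain_for(C.freq);
        y[VA_INC] = 0.0;   // end-expiration reference for alveolar volume
      }
    }

    // --------------------------- fast integration over the control step
    for (int is = 0; is < nsub; ++is) {
      M.rhs(t, y.data(), e, D, o1);
      for (int i = 0; i < NFAST; ++i) {
        k1[i] = o1.dy[i];
        ytmp[i] = y[i] + 0.5 * dt * k1[i];
      }
      M.rhs(t + 0.5 * dt, ytmp.data(), e, D, o2);
      for (int i = 0; i < NFAST; ++i) {
        k2[i] = o2.dy[i];
        ytmp[i] = y[i] + 0.5 * dt * k2[i];
      }
      M.rhs(t + 0.5 * dt, ytmp.data(), e, D, o3);
      for (int i = 0; i < NFAST; ++i) {
        k3[i] = o3.dy[i];
        ytmp[i] = y[i] + dt * k3[i];
      }
      M.rhs(t + dt, ytmp.data(), e, D, o4);
      for (int i = 0; i < NFAST; ++i) {
        k4[i] = o4.dy[i];
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
      t += dt;

      // cycle accumulators (left-endpoint sums from the k1 evaluation)
      cyc.n += 1;
      cyc.paa += o1.c.paa;
      cyc.pra += o1.c.pra;
      cyc.qlo += o1.c.qlo;
      cyc.qll += o1.c.qll_in;
      cyc.qrl += o1.c.qrl_in;
      cyc.qub += o1.c.qub_in;
      cyc.qkid += o1.c.qkid_in;
      cyc.qsp += o1.c.qsp_in;
      cyc.cart_o2 += o1.c_o2_art;
      cyc.cmv_o2 += o1.c_o2_mv;
      cyc.cart_co2 += o1.c_co2_art;
      cyc.cmv_co2 += o1.c_co2_mv;
      cyc.vsp += y[VSP];
      cyc.pintr += o1.pintr;
      cyc.o2up += o1.o2_uptake;
      cyc.co2out += o1.co2_output;
      cyc.po2alv += y[PO2ALV];
      cyc.pco2alv += y[PCO2ALV];
      cyc.afas += fas; cyc.afes += fes; cyc.afev += fev;
      double mv = o1.c.qli;
      if (o1.c.qlo < mv) mv = o1.c.qlo;
      if (o1.c.qri < mv) mv = o1.c.qri;
      if (o1.c.qro < mv) mv = o1.c.qro;
      if (o1.c.qll_out < mv) mv = o1.c.qll_out;
      if (o1.c.qrl_out < mv) mv = o1.c.qrl_out;
      if (mv < cyc.min_valve) cyc.min_valve = mv;
      if (o1.pintr < cyc.pintr_min) cyc.pintr_min = o1.pintr;

      // cardiac cycle wrap
      if (y[TC_PHASE] >= e.tc) {
        double dur = t - cyc.t0;
        double inv = 1.0 / cyc.n;
        double row[NCYC_COL] = {
          cyc.t0, t, 60.0 / dur,
          cyc.paa * inv, cyc.pra * inv,
          cyc.qlo * inv * 0.06,             // cm3/s -> l/min
          cyc.qll * inv * 0.06, cyc.qrl * inv * 0.06,
          cyc.qub * inv * 0.06, cyc.qkid * inv * 0.06, cyc.qsp * inv * 0.06,
          cyc.cart_o2 * inv, cyc.cmv_o2 * inv,
          cyc.cart_co2 * inv, cyc.cmv_co2 * inv,
          y[CDIST0 + 0], y[CDIST0 + 1], y[CDIST0 + 2], y[CDIST0 + 3],
          y[CDIST0 + 4],
          C.po2_art_prev, C.pco2_art_prev,
          C.vent, C.freq, C.tv,
          e.elmax, e.ermax, e.tc,
          e.ruba, e.rkida, e.rspa, e.rlla,
          e.vub0, e.vkid0, e.vsp0,
          cyc.vsp * inv,
          cyc.afas * inv, cyc.afes * inv, cyc.afev * inv,
          D.wl, (double) (stage_idx + 1),
          cyc.min_valve, cyc.pintr_min,
          cyc.o2up * inv * 60.0,            // mean lung O2 uptake ml/min
          cyc.co2out * inv * 60.0           // mean lung CO2 output ml/min
        };
        cycles.insert(cycles.end(), row, row + NCYC_COL);
        y[TC_PHASE] -= e.tc;
        cyc.reset(t);
      }
    }

    // time-series record
    if (t >= next_record - 1e-9) {
      FullOut orec;
      M.rhs(t, y.data(), e, D, orec);
      double row[NSER_COL] = {
        t, D.wl, orec.c.plv, orec.c.paa, orec.c.pabd, orec.c.pla,
        orec.c.pra, orec.c.pap, orec.c.qlo, orec.c.qll_in, y[VLV],
        orec.pintr, y[VLUNGS], y[PO2ALV], y[PCO2ALV],
        C.po2_art_prev, C.pco2_art_prev, C.vent, 60.0 / e.tc, e.elmax,
        fes, fev, y[CDIST0 + 3], y[VSP],
        y[VLL], orec.c.pll, orec.c.qll_in, orec.c.qll_out
      };
      series.insert(series.end(), row, row + NSER_COL);
      next_record += record_dt;
    }

    // sanity guards
    for (int i = 0; i < NFAST; ++i) {
      if (!R_finite(y[i])) { nan_abort = true; break; }
    }
    for (int i = VLA; i <= VVP; ++i) {
      if (y[i] < 0.0) ++neg_volume_events;
    }
    {
      bool debt = false;
      for (int i = 0; i < 5; ++i) if (y[CDIST0 + i] < 0.2) debt = true;
      if (debt) ++o2_debt_steps;
      for (int i = 0; i < 10; ++i) {
        if (y[CDIST0 + i] < 0.0) y[CDIST0 + i] = 0.0;
      }
    }
  }

  double blood1 = 0.0;
  for (int i = VLA; i <= VVP; ++i) blood1 += y[i];

  int ncyc = (int) (cycles.size() / NCYC_COL);
  NumericMatrix cyc_mat(ncyc, NCYC_COL);
  for (int r = 0; r < ncyc; ++r)
    for (int c = 0; c < NCYC_COL; ++c)
      cyc_mat(r, c) = cycles[r * NCYC_COL + c];
  int nser = (int) (series.size() / NSER_COL);
  NumericMatrix ser_mat(nser, NSER_COL);
  for (int r = 0; r < nser; ++r)
    for (int c = 0; c < NSER_COL; ++c)
      ser_mat(r, c) = series[r * NSER_COL + c];

  NumericVector yfin(NFAST);
  for (int i = 0; i < NFAST; ++i) yfin[i] = y[i];

  return List::create(
    _["cycles"] = cyc_mat,
    _["series"] = ser_mat,
    _["state"] = yfin,
    _["blood_volume_initial"] = blood0,
    _["blood_volume_final"] = blood1,
    _["negative_volume_events"] = neg_volume_events,
    _["o2_debt_steps"] = o2_debt_steps,
    _["nan_abort"] = nan_abort,
    _["t_final"] = t);
}
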