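// O'Hara-Rudy dynamic (ORd) human ventricular cell model, endocardial variant,
// with multiplicative conductance scaling (population of models) and fractional
// pore block (drug action). Integration uses the field-standard hybrid scheme:
// Rush-Larsen exponential updates for Hodgkin-Huxley-type gates and forward
// Euler for membrane voltage, concentrations and CaMK, with a step size
// adapted to |dV/dt|. All units: ms, mV, mM, uA/uF.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- state vector layout -------------------------------------------------
enum StateIdx {
  iV = 0, iNai, iNass, iKi, iKss, iCai, iCass, iCansr, iCajsr,
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFF, iFS, iFcaf, iFcas, iJca, iNca, iFFp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1,
  iJrelnp, iJrelp, iCaMKt,
  N_STATE
};

static const char* STATE_NAMES[N_STATE] = {
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1",
  "Jrelnp", "Jrelp", "CaMKt"
};

// Rush-Larsen states: gates in [0,1] plus nca and the two SR release fluxes
static const int RL_FIRST = iM, RL_LAST = iJrelp;

struct OrdParams {
  // multiplicative scalings on GNa, GNaL, Gto, GKr, GKs, GK1, GNCX, GNaK, PCa
  double sNa, sNaL, sto, sKr, sKs, sK1, sNCX, sNaK, sCaL;
  // fractional block on INa, INaL, Ito, IKr, IKs, IK1, ICaL
  double bNa, bNaL, bto, bKr, bKs, bK1, bCaL;
};

enum CurIdx {
  cINa = 0, cINaL, cIto, cICaL, cICaNa, cICaK, cIKr, cIKs, cIK1,
  cINaCa_i, cINaCa_ss, cINaK, cINab, cICab, cIKb, cIpCa,
  cJrel, cJup, N_CUR
};
static const char* CUR_NAMES[N_CUR] = {
  "INa", "INaL", "Ito", "ICaL", "ICaNa", "ICaK", "IKr", "IKs", "IK1",
  "INaCa_i", "INaCa_ss", "INaK", "INab", "ICab", "IKb", "IpCa",
  "Jrel", "Jup"
};

// physical constants and cell geometry (ORd)
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double Lcell = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
static const double Ageo  = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
static const double Acap  = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

// Core model evaluation at one state. Fills:
//   xinf/xtau for the Rush-Larsen states, dX for the Euler states,
//   cur[N_CUR] with the instantaneous currents/fluxes.
static void ord_eval(const double* X, const OrdParams& p, double Ist,
                     double* xinf, double* xtau, double* dX, double* cur) {
  const double v = X[iV];
  const double nai = X[iNai], nass = X[iNass];
  const double ki = X[iKi], kss = X[iKss];
  const double cai = X[iCai], cass = X[iCass];
  const double cansr = X[iCansr], cajsr = X[iCajsr];
  const double CaMKt = X[iCaMKt];

  // CaMK signalling
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05, KmCaM = 0.0015;
  const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + CaMKt;
  dX[iCaMKt] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
  const double fCaMK = 1.0 / (1.0 + KmCaMK / CaMKa);

  // reversal potentials
  const double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  const double EK  = (Rgas * Temp / Frdy) * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = (Rgas * Temp / Frdy) *
    std::log((ko + PKNa * nao) / (ki + PKNa * nai));
  double vfrt = v * Frdy / (Rgas * Temp);
  if (std::fabs(vfrt) < 1e-7) vfrt = (vfrt >= 0 ? 1e-7 : -1e-7);
  const double vffrt = vfrt * Frdy;

  // INa (fast)
  xinf[iM] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  xtau[iM] = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                    8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  xinf[iHf] = hss;
  xtau[iHf] = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                     6.149 * std::exp((v + 0.5096) / 20.27));
  xinf[iHs] = hss;
  xtau[iHs] = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                     0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 0.01;
  const double h = Ahf * X[iHf] + Ahs * X[iHs];
  xinf[iJ] = hss;
  xtau[iJ] = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                            0.3052 * std::exp((v + 0.9941) / 38.45));
  xinf[iHsp] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  xtau[iHsp] = 3.0 * xtau[iHs];
  const double hp = Ahf * X[iHf] + Ahs * X[iHsp];
  xinf[iJp] = hss;
  xtau[iJp] = 1.46 * xtau[iJ];
  const double GNa = 75.0 * p.sNa * (1.0 - p.bNa);
  const double m = X[iM];
  cur[cINa] = GNa * (v - ENa) * m * m * m *
    ((1.0 - fCaMK) * h * X[iJ] + fCaMK * hp * X[iJp]);

  // INaL (late)
  xinf[iML] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  xtau[iML] = xtau[iM];
  xinf[iHL] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  xtau[iHL] = 200.0;
  xinf[iHLp] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  xtau[iHLp] = 600.0;
  const double GNaL = 0.0075 * p.sNaL * (1.0 - p.bNaL);
  cur[cINaL] = GNaL * (v - ENa) * X[iML] *
    ((1.0 - fCaMK) * X[iHL] + fCaMK * X[iHLp]);

  // Ito
  xinf[iA] = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  xtau[iA] = 1.0515 /
    (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
     3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  // endocardial cell: delta_epi = 1
  xinf[iIF] = iss;
  xtau[iIF] = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                             0.08004 * std::exp((v + 50.0) / 16.59));
  xinf[iIS] = iss;
  xtau[iIS] = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                             1.780e-8 * std::exp((v + 114.1) / 8.079));
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double ito_i = AiF * X[iIF] + AiS * X[iIS];
  xinf[iAp] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  xtau[iAp] = xtau[iA];
  const double dti_dev = 1.354 + 1.0e-4 /
    (std::exp((v - 167.4) / 15.89) + std::exp(-(v - 12.23) / 0.2154));
  const double dti_rec = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  xinf[iIFp] = iss;
  xtau[iIFp] = dti_dev * dti_rec * xtau[iIF];
  xinf[iISp] = iss;
  xtau[iISp] = dti_dev * dti_rec * xtau[iIS];
  const double ito_ip = AiF * X[iIFp] + AiS * X[iISp];
  const double Gto = 0.02 * p.sto * (1.0 - p.bto);
  cur[cIto] = Gto * (v - EK) *
    ((1.0 - fCaMK) * X[iA] * ito_i + fCaMK * X[iAp] * ito_ip);

  // ICaL / ICaNa / ICaK
  xinf[iD] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  xtau[iD] = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                          std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  xinf[iFF] = fss;
  xtau[iFF] = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                           0.0045 * std::exp((v + 20.0) / 10.0));
  xinf[iFS] = fss;
  xtau[iFS] = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                              0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  const double f = Aff * X[iFF] + Afs * X[iFS];
  xinf[iFcaf] = fss;
  xtau[iFcaf] = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                             0.04 * std::exp((v - 4.0) / 7.0));
  xinf[iFcas] = fss;
  xtau[iFcas] = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                               0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca = Afcaf * X[iFcaf] + Afcas * X[iFcas];
  xinf[iJca] = fss;
  xtau[iJca] = 75.0;
  xinf[iFFp] = fss;
  xtau[iFFp] = 2.5 * xtau[iFF];
  const double fp = Aff * X[iFFp] + Afs * X[iFS];
  xinf[iFcafp] = fss;
  xtau[iFcafp] = 2.5 * xtau[iFcaf];
  const double fcap = Afcaf * X[iFcafp] + Afcas * X[iFcas];
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = std::max(X[iJca] * 1.0, 1e-8);
  const double tmp = 1.0 + Kmn / cass;
  const double anca = 1.0 / (k2n / km2n + tmp * tmp * tmp * tmp);
  xinf[iNca] = anca * k2n / km2n;
  xtau[iNca] = 1.0 / km2n;
  const double e2v = std::exp(2.0 * vfrt), e1v = std::exp(vfrt);
  const double PhiCaL  = 4.0 * vffrt * (cass * e2v - 0.341 * cao) / (e2v - 1.0);
  const double PhiCaNa = vffrt * (0.75 * nass * e1v - 0.75 * nao) / (e1v - 1.0);
  const double PhiCaK  = vffrt * (0.75 * kss * e1v - 0.75 * ko) / (e1v - 1.0);
  const double PCa = 0.0001 * p.sCaL * (1.0 - p.bCaL);
  const double PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  const double d_ = X[iD], nca = X[iNca], jca = X[iJca];
  const double gateCa  = f  * (1.0 - nca) + jca * fca  * nca;
  const double gateCap = fp * (1.0 - nca) + jca * fcap * nca;
  cur[cICaL]  = (1.0 - fCaMK) * PCa  * PhiCaL  * d_ * gateCa +
                fCaMK * PCap  * PhiCaL  * d_ * gateCap;
  cur[cICaNa] = (1.0 - fCaMK) * PCaNa * PhiCaNa * d_ * gateCa +
                fCaMK * PCaNap * PhiCaNa * d_ * gateCap;
  cur[cICaK]  = (1.0 - fCaMK) * PCaK * PhiCaK * d_ * gateCa +
                fCaMK * PCaKp * PhiCaK * d_ * gateCap;

  // IKr
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  xinf[iXrf] = xrss;
  xtau[iXrf] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                              4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  xinf[iXrs] = xrss;
  xtau[iXrs] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                              1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double xr = Axrf * X[iXrf] + (1.0 - Axrf) * X[iXrs];
  const double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
                     1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  const double GKr = 0.046 * p.sKr * (1.0 - p.bKr);
  cur[cIKr] = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // IKs
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  xinf[iXs1] = xs1ss;
  xtau[iXs1] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                              0.001292 * std::exp(-(v + 210.0) / 230.0));
  xinf[iXs2] = xs1ss;
  xtau[iXs2] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                      0.0193 * std::exp(-(v + 66.54) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double GKs = 0.0034 * p.sKs * (1.0 - p.bKs);
  cur[cIKs] = GKs * KsCa * X[iXs1] * X[iXs2] * (v - EKs);

  // IK1
  xinf[iXk1] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                     (1.5692 * ko + 3.8115)));
  xtau[iXk1] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                        std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  const double GK1 = 0.1908 * p.sK1 * (1.0 - p.bK1);
  cur[cIK1] = GK1 * std::sqrt(ko) * rk1 * X[iXk1] * (v - EK);

  // INaCa (Na+/Ca2+ exchanger), myoplasmic and subspace components
  {
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    const double kcaon = 1.5e6, kcaoff = 5.0e3;
    const double qna = 0.5224, qca = 0.1670;
    const double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
    const double KmCaAct = 150.0e-6;
    const double Gncx = 0.0008 * p.sNCX;
    double naX, caX, frac;
    for (int comp = 0; comp < 2; ++comp) {
      if (comp == 0) { naX = nai;  caX = cai;  frac = 0.8; }
      else           { naX = nass; caX = cass; frac = 0.2; }
      const double h1 = 1.0 + naX / kna3 * (1.0 + hna);
      const double h2 = (naX * hna) / (kna3 * h1);
      const double h3 = 1.0 / h1;
      const double h4 = 1.0 + naX / kna1 * (1.0 + naX / kna2);
      const double h5 = naX * naX / (h4 * kna1 * kna2);
      const double h6 = 1.0 / h4;
      const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
      const double h8 = nao / (kna3 * hna * h7);
      const double h9 = 1.0 / h7;
      const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
      const double h11 = nao * nao / (h10 * kna1 * kna2);
      const double h12 = 1.0 / h10;
      const double k1 = h12 * cao * kcaon;
      const double k2 = kcaoff;
      const double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
      const double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
      const double k5 = kcaoff;
      const double k6 = h6 * caX * kcaon;
      const double k7 = h5 * h2 * wna;
      const double k8 = h8 * h11 * wna;
      const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
      const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
      const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
      const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
      const double xs = x1 + x2 + x3 + x4;
      const double E1 = x1 / xs, E2 = x2 / xs, E3 = x3 / xs, E4 = x4 / xs;
      const double allo = 1.0 / (1.0 + std::pow(KmCaAct / caX, 2.0));
      const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
      const double JncxCa = E2 * k2 - E1 * k1;
      const double I = frac * Gncx * allo * (JncxNa + 2.0 * JncxCa);
      if (comp == 0) cur[cINaCa_i] = I; else cur[cINaCa_ss] = I;
    }
  }

  // INaK (Na+/K+ pump)
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    const double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    const double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    const double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2;
    const double Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
    const double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    const double t1 = 1.0 + nai / Knai, t2 = 1.0 + ki / Kki;
    const double t3 = 1.0 + nao / Knao, t4 = 1.0 + ko / Kko;
    const double denom_i = t1 * t1 * t1 + t2 * t2 - 1.0;
    const double denom_o = t3 * t3 * t3 + t4 * t4 - 1.0;
    const double a1 = k1p * std::pow(nai / Knai, 3.0) / denom_i;
    const double b1 = k1m * MgADP;
    const double a2 = k2p;
    const double b2 = k2m * std::pow(nao / Knao, 3.0) / denom_o;
    const double a3 = k3p * std::pow(ko / Kko, 2.0) / denom_o;
    const double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
    const double a4 = k4p * (MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    const double b4 = k4m * std::pow(ki / Kki, 2.0) / denom_i;
    const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a4;
    const double xs = x1 + x2 + x3 + x4;
    const double E1 = x1 / xs, E2 = x2 / xs, E3 = x3 / xs, E4 = x4 / xs;
    const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    const double Pnak = 30.0 * p.sNaK;
    cur[cINaK] = Pnak * (JnakNa + JnakK);
  }

  // background and pump currents
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  cur[cIKb] = 0.003 * xkb * (v - EK);
  {
    const double e1 = std::exp(vfrt);
    cur[cINab] = 3.75e-10 * vffrt * (nai * e1 - nao) / (e1 - 1.0);
    const double e2 = std::exp(2.0 * vfrt);
    cur[cICab] = 2.5e-8 * 4.0 * vffrt * (cai * e2 - 0.341 * cao) / (e2 - 1.0);
  }
  cur[cIpCa] = 0.0005 * cai / (0.0005 + cai);

  // SR Ca2+ release (RyR), CaMK-phosphorylated and not
  {
    const double bt = 4.75, a_rel = 0.5 * bt;
    const double c8 = std::pow(1.5 / cajsr, 8.0);
    double Jrel_inf = a_rel * (-cur[cICaL]) / (1.0 + c8);
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    xinf[iJrelnp] = Jrel_inf;
    xtau[iJrelnp] = tau_rel;
    const double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-cur[cICaL]) / (1.0 + c8);
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    xinf[iJrelp] = Jrel_infp;
    xtau[iJrelp] = tau_relp;
    cur[cJrel] = (1.0 - fCaMK) * X[iJrelnp] + fCaMK * X[iJrelp];
  }

  // SERCA uptake, leak, NSR->JSR translocation
  const double Jupnp = 0.004375 * cai / (cai + 0.00092);
  const double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  const double Jleak = 0.0039375 * cansr / 15.0;
  cur[cJup] = (1.0 - fCaMK) * Jupnp + fCaMK * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  // ionic diffusion between subspace and myoplasm
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // concentration balances
  dX[iNai] = -(cur[cINa] + cur[cINaL] + 3.0 * cur[cINaCa_i] +
               3.0 * cur[cINaK] + cur[cINab]) * Acap / (Frdy * vmyo) +
             JdiffNa * vss / vmyo;
  dX[iNass] = -(cur[cICaNa] + 3.0 * cur[cINaCa_ss]) * Acap / (Frdy * vss) -
              JdiffNa;
  dX[iKi] = -(cur[cIto] + cur[cIKr] + cur[cIKs] + cur[cIK1] + cur[cIKb] +
              Ist - 2.0 * cur[cINaK]) * Acap / (Frdy * vmyo) +
            JdiffK * vss / vmyo;
  dX[iKss] = -cur[cICaK] * Acap / (Frdy * vss) - JdiffK;

  const double cmdnmax = 0.05, kmcmdn = 0.00238;
  const double trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  const double bc1 = kmcmdn + cai, bc2 = kmtrpn + cai;
  const double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (bc1 * bc1) +
                             trpnmax * kmtrpn / (bc2 * bc2));
  dX[iCai] = Bcai * (-(cur[cIpCa] + cur[cICab] - 2.0 * cur[cINaCa_i]) *
                     Acap / (2.0 * Frdy * vmyo) -
                     cur[cJup] * vnsr / vmyo + Jdiff * vss / vmyo);
  const double bs1 = KmBSR + cass, bs2 = KmBSL + cass;
  const double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (bs1 * bs1) +
                              BSLmax * KmBSL / (bs2 * bs2));
  dX[iCass] = Bcass * (-(cur[cICaL] - 2.0 * cur[cINaCa_ss]) *
                       Acap / (2.0 * Frdy * vss) +
                       cur[cJrel] * vjsr / vss - Jdiff);
  dX[iCansr] = cur[cJup] - Jtr * vjsr / vnsr;
  const double bj = kmcsqn + cajsr;
  const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (bj * bj));
  dX[iCajsr] = Bcajsr * (Jtr - cur[cJrel]);

  // membrane potential
  dX[iV] = -(cur[cINa] + cur[cINaL] + cur[cIto] + cur[cICaL] + cur[cICaNa] +
             cur[cICaK] + cur[cIKr] + cur[cIKs] + cur[cIK1] +
             cur[cINaCa_i] + cur[cINaCa_ss] + cur[cINaK] + cur[cINab] +
             cur[cIKb] + cur[cIpCa] + cur[cICab] + Ist);
}

static OrdParams params_from(const NumericVector& scal,
                             const NumericVector& blk) {
  if (scal.size() != 9) stop("expected 9 conductance scaling factors");
  if (blk.size() != 7) stop("expected 7 block fractions");
  OrdParams p;
  p.sNa = scal[0]; p.sNaL = scal[1]; p.sto = scal[2]; p.sKr = scal[3];
  p.sKs = scal[4]; p.sK1 = scal[5]; p.sNCX = scal[6]; p.sNaK = scal[7];
  p.sCaL = scal[8];
  p.bNa = blk[0]; p.bNaL = blk[1]; p.bto = blk[2]; p.bKr = blk[3];
  p.bKs = blk[4]; p.bK1 = blk[5]; p.bCaL = blk[6];
  for (int i = 0; i < 9; ++i)
    if (scal[i] < 0 || !R_finite(scal[i])) stop("scaling factors must be finite and >= 0");
  for (int i = 0; i < 7; ++i)
    if (blk[i] < 0 || blk[i] > 1 || !R_finite(blk[i])) stop("block fractions must lie in [0,1]");
  return p;
}

// [[Rcpp::export]]
CharacterVector ord_state_names_cpp() {
  CharacterVector out(N_STATE);
  for (int i = 0; i < N_STATE; ++i) out[i] = STATE_NAMES[i];
  return out;
}

// [[Rcpp::export]]
NumericVector ord_default_state_cpp() {
  NumericVector x(N_STATE);
  x[iV] = -87.0; x[iNai] = 7.0; x[iNass] = 7.0; x[iKi] = 145.0; x[iKss] = 145.0;
  x[iCai] = 1.0e-4; x[iCass] = 1.0e-4; x[iCansr] = 1.2; x[iCajsr] = 1.2;
  x[iM] = 0.0; x[iHf] = 1.0; x[iHs] = 1.0; x[iJ] = 1.0; x[iHsp] = 1.0;
  x[iJp] = 1.0; x[iML] = 0.0; x[iHL] = 1.0; x[iHLp] = 1.0;
  x[iA] = 0.0; x[iIF] = 1.0; x[iIS] = 1.0; x[iAp] = 0.0; x[iIFp] = 1.0;
  x[iISp] = 1.0; x[iD] = 0.0; x[iFF] = 1.0; x[iFS] = 1.0; x[iFcaf] = 1.0;
  x[iFcas] = 1.0; x[iJca] = 1.0; x[iNca] = 0.0; x[iFFp] = 1.0;
  x[iFcafp] = 1.0; x[iXrf] = 0.0; x[iXrs] = 0.0; x[iXs1] = 0.0;
  x[iXs2] = 0.0; x[iXk1] = 1.0; x[iJrelnp] = 0.0; x[iJrelp] = 0.0;
  x[iCaMKt] = 0.0;
  x.attr("names") = ord_state_names_cpp();
  return x;
}

// Time derivatives of all state variables (gates as (inf - x)/tau), with the
// instantaneous current decomposition attached as attribute "currents".
// [[Rcpp::export]]
NumericVector ord_rhs_cpp(NumericVector state, NumericVector scalings,
                          NumericVector blocks, double Ist) {
  if (state.size() != N_STATE) stop("state vector must have %d components", N_STATE);
  for (int i = 0; i < N_STATE; ++i)
    if (!R_finite(state[i]))
      stop("non-finite state component '%s'", STATE_NAMES[i]);
  OrdParams p = params_from(scalings, blocks);
  double xinf[N_STATE], xtau[N_STATE], dX[N_STATE], cur[N_CUR];
  ord_eval(REAL(state), p, Ist, xinf, xtau, dX, cur);
  NumericVector out(N_STATE);
  for (int i = 0; i < N_STATE; ++i) {
    if (i >= RL_FIRST && i <= RL_LAST)
      out[i] = (xinf[i] - state[i]) / xtau[i];
    else
      out[i] = dX[i];
  }
  out.attr("names") = ord_state_names_cpp();
  NumericVector cv(N_CUR);
  for (int i = 0; i < N_CUR; ++i) cv[i] = cur[i];
  CharacterVector cn(N_CUR);
  for (int i = 0; i < N_CUR; ++i) cn[i] = CUR_NAMES[i];
  cv.attr("names") = cn;
  out.attr("currents") = cv;
  return out;
}

// Paced simulation: `beats` cycles of length `cl` ms with a square stimulus of
// `stim_amp` uA/uF for `stim_dur` ms at the start of each cycle. Records the
// final beat (time within cycle, voltage, subspace-free cytosolic Ca2+) at the
// solver's own adaptive grid. Returns the trace, the final state, and a status.
// [[Rcpp::export]]
List ord_simulate_cpp(NumericVector state0, NumericVector scalings,
                      NumericVector blocks, double cl, int beats,
                      double stim_amp, double stim_dur,
                      double dt_min, double dt_max, double dv_step) {
  if (state0.size() != N_STATE) stop("state vector must have %d components", N_STATE);
  if (cl <= 0 || beats < 1) stop("invalid pacing protocol");
  if (dt_min <= 0 || dt_max < dt_min || dv_step <= 0) stop("invalid solver settings");
  OrdParams p = params_from(scalings, blocks);

  double X[N_STATE];
  for (int i = 0; i < N_STATE; ++i) X[i] = state0[i];
  double xinf[N_STATE], xtau[N_STATE], dX[N_STATE], cur[N_CUR];

  std::vector<double> rec_t, rec_v, rec_ca;
  int status = 0, fail_beat = -1;

  for (int beat = 0; beat < beats && status == 0; ++beat) {
    const bool record = (beat == beats - 1);
    double t = 0.0;
    if (record) {
      rec_t.reserve(8192);
      rec_t.push_back(0.0); rec_v.push_back(X[iV]); rec_ca.push_back(X[iCai]);
    }
    while (t < cl) {
      const bool in_stim = (t < stim_dur);
      const double Ist = in_stim ? stim_amp : 0.0;
      ord_eval(X, p, Ist, xinf, xtau, dX, cur);

      double dt = dv_step / (std::fabs(dX[iV]) + 1e-12);
      // the subspace Ca2+ and junctional SR are the stiffest non-gate
      // states and can move fast while V is quiet (release, EAD dynamics):
      // cap their per-step relative change at 20%
      const double dt_ca = 0.2 * X[iCass] / (std::fabs(dX[iCass]) + 1e-12);
      const double dt_jsr = 0.2 * X[iCajsr] / (std::fabs(dX[iCajsr]) + 1e-12);
      if (dt_ca < dt) dt = dt_ca;
      if (dt_jsr < dt) dt = dt_jsr;
      if (dt > dt_max) dt = dt_max;
      if (dt < dt_min) dt = dt_min;
      if (in_stim && t + dt > stim_dur) dt = stim_dur - t;
      if (t + dt > cl) dt = cl - t;
      if (dt < 1e-9) dt = 1e-9;

      // Rush-Larsen for the gate-like states; Heun (predictor-corrector,
      // second order) for voltage, concentrations and CaMK, whose slow
      // first-order error otherwise biases the Ca2+-transient durations.
      // If the predictor leaves the admissible region the step is retried
      // at half size (fast excursions occasionally outrun the V-based
      // step control in low-repolarisation-reserve models).
      double Xp[N_STATE];
      bool expstep[N_STATE] = {false};
      for (int attempt = 0; ; ++attempt) {
        bool ok = true;
        for (int i = 0; i < N_STATE; ++i) {
          expstep[i] = false;
          if (i >= RL_FIRST && i <= RL_LAST) {
            Xp[i] = xinf[i] + (X[i] - xinf[i]) * std::exp(-dt / xtau[i]);
            if (i <= iXk1) {
              // gates and nca are fractions; RL overshoots only by rounding
              if (Xp[i] < 0.0) Xp[i] = 0.0;
              if (Xp[i] > 1.0) Xp[i] = 1.0;
            }
          } else if (i >= iNai && i <= iCajsr && dX[i] < 0.0 &&
                     -dX[i] * dt > 0.15 * X[i]) {
            // fast relative decay of a concentration (e.g. junctional SR
            // depletion during release): additive steps overshoot through
            // zero, the exponential update respects positivity and the
            // stiff approach to the depleted quasi-equilibrium
            Xp[i] = X[i] * std::exp(dt * dX[i] / X[i]);
            expstep[i] = true;
          } else {
            Xp[i] = X[i] + dt * dX[i];
          }
          if (!R_finite(Xp[i])) ok = false;
        }
        if (ok && (Xp[iCai] <= 0.0 || Xp[iCass] <= 0.0 || Xp[iCajsr] <= 0.0 ||
                   Xp[iCansr] <= 0.0 || Xp[iNai] <= 0.0 || Xp[iKi] <= 0.0 ||
                   Xp[iKss] <= 0.0 || Xp[iNass] <= 0.0))
          ok = false;
        // a voltage jump far beyond the target means the dynamics outran
        // the derivative-based control (step-doubling verification)
        if (ok && dt > dt_min &&
            std::fabs(Xp[iV] - X[iV]) > std::max(3.0, 15.0 * dv_step))
          ok = false;
        if (ok || attempt >= 12 || dt <= 1e-7) break;
        dt *= 0.5;
      }
      {
        const double t_mid = t + dt;
        const double Ist2 = (t_mid < stim_dur) ? stim_amp : 0.0;
        double xinf2[N_STATE], xtau2[N_STATE], dX2[N_STATE], cur2[N_CUR];
        bool ok = true;
        for (int i = 0; i < N_STATE && ok; ++i)
          if (!R_finite(Xp[i])) ok = false;
        if (ok && Xp[iCai] > 0.0 && Xp[iCass] > 0.0 && Xp[iCajsr] > 0.0 &&
            Xp[iCansr] > 0.0 && Xp[iNai] > 0.0 && Xp[iKi] > 0.0) {
          ord_eval(Xp, p, Ist2, xinf2, xtau2, dX2, cur2);
          for (int i = 0; i < N_STATE; ++i) {
            if ((i >= RL_FIRST && i <= RL_LAST) || expstep[i]) X[i] = Xp[i];
            else {
              X[i] = X[i] + 0.5 * dt * (dX[i] + dX2[i]);
              // the corrector must not cross an axis the predictor respected
              if ((i >= iNai && i <= iCajsr) && X[i] <= 0.0)
                X[i] = 0.5 * Xp[i];
            }
          }
        } else {
          // irrecoverable: keep the bad step so the failure check reports it
          for (int i = 0; i < N_STATE; ++i) X[i] = Xp[i];
        }
      }
      t += dt;

      if (!R_finite(X[iV]) || X[iCai] <= 0.0 || X[iCajsr] <= 0.0 ||
          X[iNai] <= 0.0 || X[iKi] <= 0.0) {
        status = 1; fail_beat = beat + 1; break;
      }
      if (record) {
        rec_t.push_back(t); rec_v.push_back(X[iV]); rec_ca.push_back(X[iCai]);
      }
    }
  }

  NumericVector fs(N_STATE);
  for (int i = 0; i < N_STATE; ++i) fs[i] = X[i];
  fs.attr("names") = ord_state_names_cpp();
  return List::create(
    _["time"] = wrap(rec_t), _["v"] = wrap(rec_v), _["cai"] = wrap(rec_ca),
    _["final_state"] = fs, _["status"] = status, _["fail_beat"] = fail_beat);
}
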