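// Human ventricular myocyte electrophysiology (O'Hara et al. model, endocardial
// variant) with per-cell conductance scaling for population-of-models runs.
// Gates advance by Rush-Larsen; voltage and concentrations by forward Euler on
// an adaptive two-level time step bounded so |dV| per step stays small.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double nao = 140.0, cao = 1.8, ko = 5.4;
const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

// cell geometry (published values; 3.14 kept as in the reference code)
const double Lcell = 0.01, rad = 0.0011;
const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
const double Acap = 2.0 * Ageo;
const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

struct State {
  double v, nai, nass, ki, kss, cai, cass, cansr, cajsr;
  double m, hf, hs, j, hsp, jp, mL, hL, hLp;
  double a, iF, iS, ap, iFp, iSp;
  double d, ff, fs, fcaf, fcas, jca, nca, ffp, fcafp;
  double xrf, xrs, xs1, xs2, xk1;
  double Jrelnp, Jrelp, CaMKt;
};

State init_state() {
  State s;
  s.v = -87.0; s.nai = 7.0; s.nass = 7.0; s.ki = 145.0; s.kss = 145.0;
  s.cai = 1.0e-4; s.cass = 1.0e-4; s.cansr = 1.2; s.cajsr = 1.2;
  s.m = 0.0; s.hf = 1.0; s.hs = 1.0; s.j = 1.0; s.hsp = 1.0; s.jp = 1.0;
  s.mL = 0.0; s.hL = 1.0; s.hLp = 1.0;
  s.a = 0.0; s.iF = 1.0; s.iS = 1.0; s.ap = 0.0; s.iFp = 1.0; s.iSp = 1.0;
  s.d = 0.0; s.ff = 1.0; s.fs = 1.0; s.fcaf = 1.0; s.fcas = 1.0; s.jca = 1.0;
  s.nca = 0.0; s.ffp = 1.0; s.fcafp = 1.0;
  s.xrf = 0.0; s.xrs = 0.0; s.xs1 = 0.0; s.xs2 = 0.0; s.xk1 = 1.0;
  s.Jrelnp = 0.0; s.Jrelp = 0.0; s.CaMKt = 0.0;
  return s;
}

struct Scales { double gNa, gNaL, gto, pCa, gKr, gKs, gK1; };

struct Deriv {
  // time derivatives of Euler states and (inf, tau) of Rush-Larsen states
  double dv, dnai, dnass, dki, dkss, dcai, dcass, dcansr, dcajsr;
  double dnca, dCaMKt;
  double minf, tm, hinf, thf, ths, jinf, tj, hspinf, thsp, tjp;
  double mLinf, tmL, hLinf, thL, hLpinf, thLp;
  double ainf, ta, iinf, tiF, tiS, apinf, tiFp, tiSp;
  double dinf, td, finf, tff, tfs, fcainf, tfcaf, tfcas, tjca, tffp, tfcafp;
  double xrinf, txrf, txrs, xs1inf, txs1, txs2, xk1inf, txk1;
  double relnpinf, trelnp, relpinf, trelp;
};

inline double sq(double x) { return x * x; }

// all membrane currents and fluxes at the current state
Deriv rhs(const State& s, const Scales& sc, double Istim) {
  Deriv d;
  double v = s.v;
  const double F = Frdy, R = Rgas, T = Temp;

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05, KmCaM = 0.0015;
  double CaMKb = CaMKo * (1.0 - s.CaMKt) / (1.0 + KmCaM / s.cass);
  double CaMKa = CaMKb + s.CaMKt;
  d.dCaMKt = aCaMK * CaMKb * (CaMKb + s.CaMKt) - bCaMK * s.CaMKt;
  double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

  double ENa = (R * T / F) * std::log(nao / s.nai);
  double EK = (R * T / F) * std::log(ko / s.ki);
  const double PKNa = 0.01833;
  double EKs = (R * T / F) * std::log((ko + PKNa * nao) / (s.ki + PKNa * s.nai));
  double vf = v;
  if (std::fabs(vf) < 1e-6) vf = 1e-6;  // GHK singularity guard
  double vffrt = vf * F * F / (R * T);
  double vfrt = vf * F / (R * T);

  // INa
  d.minf = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  d.tm = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                8.552 * std::exp(-(v + 77.42) / 5.955));
  d.hinf = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  d.thf = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                 6.149 * std::exp((v + 0.5096) / 20.27));
  d.ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                 0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 0.01;
  double h = Ahf * s.hf + Ahs * s.hs;
  d.jinf = d.hinf;
  d.tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                        0.3052 * std::exp((v + 0.9941) / 38.45));
  d.hspinf = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  d.thsp = 3.0 * d.ths;
  d.tjp = 1.46 * d.tj;
  double hp = Ahf * s.hf + Ahs * s.hsp;
  double GNa = 75.0 * sc.gNa;
  double INa = GNa * (v - ENa) * s.m * s.m * s.m *
               ((1.0 - fphos) * h * s.j + fphos * hp * s.jp);

  // INaL
  d.mLinf = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  d.tmL = d.tm;
  d.hLinf = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  d.thL = 200.0;
  d.hLpinf = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  d.thLp = 3.0 * d.thL;
  double GNaL = 0.0075 * sc.gNaL;
  double INaL = GNaL * (v - ENa) * s.mL *
                ((1.0 - fphos) * s.hL + fphos * s.hLp);

  // Ito
  d.ainf = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  d.ta = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                   3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  d.iinf = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  d.tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                         0.08004 * std::exp((v + 50.0) / 16.59));
  d.tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                         1.780e-8 * std::exp((v + 114.1) / 8.079));
  double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  double AiS = 1.0 - AiF;
  double ii = AiF * s.iF + AiS * s.iS;
  d.apinf = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  double dti_dev = 1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                                     std::exp(-(v - 12.23) / 0.2154));
  double dti_rec = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  d.tiFp = dti_dev * dti_rec * d.tiF;
  d.tiSp = dti_dev * dti_rec * d.tiS;
  double ip = AiF * s.iFp + AiS * s.iSp;
  double Gto = 0.02 * sc.gto;
  double Ito = Gto * (v - EK) * ((1.0 - fphos) * s.a * ii + fphos * s.ap * ip);

  // ICaL / ICaNa / ICaK
  d.dinf = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  d.td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) + std::exp(0.09 * (v + 14.0)));
  d.finf = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  d.tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                       0.0045 * std::exp((v + 20.0) / 10.0));
  d.tfs = 1000.0 + 1.0 / (3.5e-5 * std::exp(-(v + 5.0) / 4.0) +
                          3.5e-5 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  double f = Aff * s.ff + Afs * s.fs;
  d.fcainf = d.finf;
  d.tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                         0.04 * std::exp((v - 4.0) / 7.0));
  d.tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                           0.00012 * std::exp(v / 7.0));
  double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  double Afcas = 1.0 - Afcaf;
  double fca = Afcaf * s.fcaf + Afcas * s.fcas;
  d.tjca = 75.0;
  d.tffp = 2.5 * d.tff;
  double fp = Aff * s.ffp + Afs * s.fs;
  d.tfcafp = 2.5 * d.tfcaf;
  double fcap = Afcaf * s.fcafp + Afcas * s.fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = s.jca * 1.0;
  double anca = 1.0 / (k2n / km2n + std::pow(1.0 + Kmn / s.cass, 4.0));
  d.dnca = anca * k2n - s.nca * km2n;
  double e2 = std::exp(2.0 * vfrt), e1 = std::exp(vfrt);
  double PhiCaL = 4.0 * vffrt * (s.cass * e2 - 0.341 * cao) / (e2 - 1.0);
  double PhiCaNa = vffrt * (0.75 * s.nass * e1 - 0.75 * nao) / (e1 - 1.0);
  double PhiCaK = vffrt * (0.75 * s.kss * e1 - 0.75 * ko) / (e1 - 1.0);
  double PCa = 0.0001 * sc.pCa;
  double PCap = 1.1 * PCa;
  double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  double gate_np = s.d * (f * (1.0 - s.nca) + s.jca * fca * s.nca);
  double gate_p = s.d * (fp * (1.0 - s.nca) + s.jca * fcap * s.nca);
  double ICaL = (1.0 - fphos) * PCa * PhiCaL * gate_np +
                fphos * PCap * PhiCaL * gate_p;
  double ICaNa = (1.0 - fphos) * PCaNa * PhiCaNa * gate_np +
                 fphos * PCaNap * PhiCaNa * gate_p;
  double ICaK = (1.0 - fphos) * PCaK * PhiCaK * gate_np +
                fphos * PCaKp * PhiCaK * gate_p;

  // IKr
  d.xrinf = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  d.txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                          4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  d.txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                          1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  double Axrs = 1.0 - Axrf;
  double xr = Axrf * s.xrf + Axrs * s.xrs;
  double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
               1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  double GKr = 0.046 * sc.gKr;
  double IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // IKs
  d.xs1inf = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  d.txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                          0.001292 * std::exp(-(v + 210.0) / 230.0));
  d.txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                  0.0193 * std::exp(-(v + 66.54) / 31.0));
  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / s.cai, 1.4));
  double GKs = 0.0034 * sc.gKs;
  double IKs = GKs * KsCa * s.xs1 * s.xs2 * (v - EKs);

  // IK1
  d.xk1inf = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                   (1.5692 * ko + 3.8115)));
  d.txk1 = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                    std::exp((v + 236.8) / 69.33));
  double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  double GK1 = 0.1908 * sc.gK1;
  double IK1 = GK1 * std::sqrt(ko) * rk1 * s.xk1 * (v - EK);

  // INaCa (myoplasmic and subspace components)
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3, qna = 0.5224, qca = 0.1670;
  double hca = std::exp(qca * v * F / (R * T));
  double hna = std::exp(qna * v * F / (R * T));
  const double KmCaAct = 150.0e-6;
  double Gncx = 0.0008;
  double INaCa_i, INaCa_ss;
  {
    double nai_ = s.nai, cai_ = s.cai;
    double h1 = 1.0 + nai_ / kna3 * (1.0 + hna);
    double h2 = (nai_ * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nai_ / kna1 * (1.0 + nai_ / kna2);
    double h5 = nai_ * nai_ / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cai_ * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    double allo = 1.0 / (1.0 + sq(KmCaAct / cai_));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (JncxNa + 2.0 * JncxCa);
  }
  {
    double nai_ = s.nass, cai_ = s.cass;
    double h1 = 1.0 + nai_ / kna3 * (1.0 + hna);
    double h2 = (nai_ * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nai_ / kna1 * (1.0 + nai_ / kna2);
    double h5 = nai_ * nai_ / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon, k2 = kcaoff;
    double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    double k5 = kcaoff, k6 = h6 * cai_ * kcaon;
    double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    double allo = 1.0 / (1.0 + sq(KmCaAct / cai_));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (JncxNa + 2.0 * JncxCa);
  }

  // INaK
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    double Knai = Knai0 * std::exp(delta * v * F / (3.0 * R * T));
    double Knao = Knao0 * std::exp((1.0 - delta) * v * F / (3.0 * R * T));
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    const double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2;
    const double Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
    double P = eP / (1.0 + H / Khp + s.nai / Knap + s.ki / Kxkur);
    double a1 = (k1p * std::pow(s.nai / Knai, 3.0)) /
                (std::pow(1.0 + s.nai / Knai, 3.0) +
                 sq(1.0 + s.ki / Kki) - 1.0);
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = (k2m * std::pow(nao / Knao, 3.0)) /
                (std::pow(1.0 + nao / Knao, 3.0) + sq(1.0 + ko / Kko) - 1.0);
    double a3 = (k3p * sq(ko / Kko)) /
                (std::pow(1.0 + nao / Knao, 3.0) + sq(1.0 + ko / Kko) - 1.0);
    double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
    double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    double b4 = (k4m * sq(s.ki / Kki)) /
                (std::pow(1.0 + s.nai / Knai, 3.0) + sq(1.0 + s.ki / Kki) - 1.0);
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a4;
    double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    const double Pnak = 30.0;
    INaK = Pnak * (JnakNa + JnakK);
  }

  // background and pump currents
  double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  double IKb = 0.003 * xkb * (v - EK);
  double INab = 3.75e-10 * vffrt * (s.nai * e1 - nao) / (e1 - 1.0);
  double ICab = 2.5e-8 * 4.0 * vffrt * (s.cai * e2 - 0.341 * cao) / (e2 - 1.0);
  double IpCa = 0.0005 * s.cai / (0.0005 + s.cai);

  // diffusion fluxes
  double JdiffNa = (s.nass - s.nai) / 2.0;
  double JdiffK = (s.kss - s.ki) / 2.0;
  double Jdiff = (s.cass - s.cai) / 0.2;

  // SR release (RyR), with CaMK-phosphorylated pathway
  const double bt = 4.75;
  double a_rel = 0.5 * bt;
  d.relnpinf = a_rel * (-ICaL) / (1.0 + std::pow(1.5 / s.cajsr, 8.0));
  d.trelnp = bt / (1.0 + 0.0123 / s.cajsr);
  if (d.trelnp < 0.001) d.trelnp = 0.001;
  const double btp = 1.25 * bt;
  double a_relp = 0.5 * btp;
  d.relpinf = a_relp * (-ICaL) / (1.0 + std::pow(1.5 / s.cajsr, 8.0));
  d.trelp = btp / (1.0 + 0.0123 / s.cajsr);
  if (d.trelp < 0.001) d.trelp = 0.001;
  double Jrel = (1.0 - fphos) * s.Jrelnp + fphos * s.Jrelp;

  // SR uptake and translocation
  double Jupnp = 0.004375 * s.cai / (s.cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * s.cai / (s.cai + 0.00092 - 0.00017);
  double Jleak = 0.0039375 * s.cansr / 15.0;
  double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
  double Jtr = (s.cansr - s.cajsr) / 100.0;

  // concentration balances (buffered for Ca)
  d.dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
               (F * vmyo) +
           JdiffNa * vss / vmyo;
  d.dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa;
  d.dki = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) * Acap /
              (F * vmyo) +
          JdiffK * vss / vmyo;
  d.dkss = -ICaK * Acap / (F * vss) - JdiffK;
  const double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07,
               kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / sq(kmcmdn + s.cai) +
                       trpnmax * kmtrpn / sq(kmtrpn + s.cai));
  d.dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * F * vmyo) -
                   Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / sq(KmBSR + s.cass) +
                        BSLmax * KmBSL / sq(KmBSL + s.cass));
  d.dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F * vss) +
                     Jrel * vjsr / vss - Jdiff);
  d.dcansr = Jup - Jtr * vjsr / vnsr;
  double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / sq(kmcsqn + s.cajsr));
  d.dcajsr = Bcajsr * (Jtr - Jrel);

  d.dv = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
           INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);
  return d;
}

inline double rl(double y, double yinf, double tau, double dt) {
  return yinf + (y - yinf) * std::exp(-dt / tau);
}

void advance(State& s, const Deriv& d, double dt) {
  s.v += dt * d.dv;
  s.nai += dt * d.dnai;
  s.nass += dt * d.dnass;
  s.ki += dt * d.dki;
  s.kss += dt * d.dkss;
  s.cai += dt * d.dcai;
  s.cass += dt * d.dcass;
  s.cansr += dt * d.dcansr;
  s.cajsr += dt * d.dcajsr;
  s.nca += dt * d.dnca;
  s.CaMKt += dt * d.dCaMKt;
  s.m = rl(s.m, d.minf, d.tm, dt);
  s.hf = rl(s.hf, d.hinf, d.thf, dt);
  s.hs = rl(s.hs, d.hinf, d.ths, dt);
  s.j = rl(s.j, d.jinf, d.tj, dt);
  s.hsp = rl(s.hsp, d.hspinf, d.thsp, dt);
  s.jp = rl(s.jp, d.jinf, d.tjp, dt);
  s.mL = rl(s.mL, d.mLinf, d.tmL, dt);
  s.hL = rl(s.hL, d.hLinf, d.thL, dt);
  s.hLp = rl(s.hLp, d.hLpinf, d.thLp, dt);
  s.a = rl(s.a, d.ainf, d.ta, dt);
  s.iF = rl(s.iF, d.iinf, d.tiF, dt);
  s.iS = rl(s.iS, d.iinf, d.tiS, dt);
  s.ap = rl(s.ap, d.apinf, d.ta, dt);
  s.iFp = rl(s.iFp, d.iinf, d.tiFp, dt);
  s.iSp = rl(s.iSp, d.iinf, d.tiSp, dt);
  s.d = rl(s.d, d.dinf, d.td, dt);
  s.ff = rl(s.ff, d.finf, d.tff, dt);
  s.fs = rl(s.fs, d.finf, d.tfs, dt);
  s.fcaf = rl(s.fcaf, d.fcainf, d.tfcaf, dt);
  s.fcas = rl(s.fcas, d.fcainf, d.tfcas, dt);
  s.jca = rl(s.jca, d.fcainf, d.tjca, dt);
  s.ffp = rl(s.ffp, d.finf, d.tffp, dt);
  s.fcafp = rl(s.fcafp, d.fcainf, d.tfcafp, dt);
  s.xrf = rl(s.xrf, d.xrinf, d.txrf, dt);
  s.xrs = rl(s.xrs, d.xrinf, d.txrs, dt);
  s.xs1 = rl(s.xs1, d.xs1inf, d.txs1, dt);
  s.xs2 = rl(s.xs2, d.xs1inf, d.txs2, dt);
  s.xk1 = rl(s.xk1, d.xk1inf, d.txk1, dt);
  s.Jrelnp = rl(s.Jrelnp, d.relnpinf, d.trelnp, dt);
  s.Jrelp = rl(s.Jrelp, d.relpinf, d.trelp, dt);
}

bool finite_state(const State& s) {
  return R_finite(s.v) && R_finite(s.cai) && R_finite(s.nai) &&
         R_finite(s.cajsr) && R_finite(s.cass) && R_finite(s.ki);
}

}  // namespace

//' @name ord_simulate_cpp
//' @title Low-level paced single-cell run of the ventricular AP model
//' @noRd
// [[Rcpp::export(name = ".ord_simulate_cpp")]]
List ord_simulate_cpp(NumericVector scales, double cl, int n_beats,
                      double output_dt, double dt_min, double dt_max,
                      double dv_max, int stim_mode, double v_bump,
                      double stim_amp, double stim_dur) {
  if (scales.size() != 7) stop("scales must have length 7");
  Scales sc;
  sc.gNa = scales[0]; sc.gNaL = scales[1]; sc.gto = scales[2];
  sc.pCa = scales[3]; sc.gKr = scales[4]; sc.gKs = scales[5];
  sc.gK1 = scales[6];

  State s = init_state();
  double t_end = cl * n_beats;
  int n_out = (int)std::floor(t_end / output_dt + 1e-9);
  NumericVector vout(n_out, NA_REAL);
  NumericVector peak_v(n_beats, R_NegInf);
  NumericVector v_diastole(n_beats, NA_REAL);

  double t = 0.0;
  int beat = -1;
  int i_out = 0;
  bool blown = false;

  while (t < t_end - 1e-9 && !blown) {
    // stimulus boundaries
    int beat_now = (int)std::floor(t / cl + 1e-9);
    if (beat_now > beat) {
      if (beat >= 0) v_diastole[beat] = s.v;  // value just before next stimulus
      beat = beat_now;
      if (stim_mode == 1) s.v += v_bump;
    }
    double t_next_stim = (beat + 1) * cl;

    double Istim = 0.0;
    if (stim_mode == 2 && (t - beat * cl) < stim_dur) Istim = stim_amp;

    Deriv d = rhs(s, sc, Istim);
    double dt = dt_max;
    double adv = std::fabs(d.dv);
    if (adv > 1e-12) dt = dv_max / adv;
    if (dt > dt_max) dt = dt_max;
    if (dt < dt_min) dt = dt_min;
    // do not step over output samples or the next stimulus
    double t_next_out = (i_out < n_out) ? i_out * output_dt : t_end;
    if (t + dt > t_next_stim) dt = t_next_stim - t;
    if (t >= t_next_out - 1e-9 && i_out < n_out) {
      vout[i_out] = s.v;
      ++i_out;
      t_next_out = (i_out < n_out) ? i_out * output_dt : t_end;
    }
    if (t + dt > t_next_out) dt = t_next_out - t;
    if (dt < 1e-9) dt = 1e-9;
    advance(s, d, dt);
    t += dt;
    if (!finite_state(s)) { blown = true; break; }
    if (s.v > peak_v[beat]) peak_v[beat] = s.v;
  }
  if (!blown && beat >= 0 && beat < n_beats) v_diastole[beat] = s.v;
  // fill any trailing samples (t_end boundary)
  while (!blown && i_out < n_out) { vout[i_out] = s.v; ++i_out; }

  return List::create(
      _["v"] = vout, _["output_dt"] = output_dt, _["cl"] = cl,
      _["n_beats"] = n_beats, _["peak_v"] = peak_v,
      _["v_diastole"] = v_diastole, _["ok"] = !blown,
      _["v_final"] = s.v);
}

//' @name ord_state_drift_cpp
//' @title Quiescent run returning start/end voltage for equilibrium checks
//' @noRd
// [[Rcpp::export(name = ".ord_drift_cpp")]]
NumericVector ord_drift_cpp(NumericVector scales, double duration,
                            double dt_min, double dt_max, double dv_max) {
  List r = ord_simulate_cpp(scales, duration, 1, duration / 2.0, dt_min,
                            dt_max, dv_max, 0, 0.0, 0.0, 0.0);
  NumericVector v = r["v"];
  double vf = r["v_final"];
  return NumericVector::create(v[0], vf);
}
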