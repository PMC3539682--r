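// Ionic cell models of the human atrial myocyte and explicit integrators.
//
// Models implemented from their original publications (standard CellML
// parameterizations):
//   id 0: Courtemanche, Ramirez & Nattel 1998, Am J Physiol 275:H301-H321.
//   id 1: Nygren et al. 1998, Circ Res 82:63-81.
//   id 2: Maleckar et al. 2009, Am J Physiol 297:H1398-H1410 (Nygren lineage:
//         reformulated I_t/I_Kur, no electroneutral Na influx, optional I_KACh).
//   id 3: mock excitable cell (two-variable Mitchell-Schaeffer kinetics mapped
//         onto a configurable voltage range) used as a protocol test double.
//
// State convention: y[0] is V_m in mV.  Hodgkin-Huxley gates are advanced with
// the Rush-Larsen exponential update y <- y_inf + (y - y_inf) exp(-dt/tau);
// all remaining states with forward Euler; an optional per-state RK4
// sub-integrator override is available for stiff plugin states.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#define MAXSTATE 32
#define NCUR 12   // INa IbNa ICaL IbCa INCX INKA IPMCA Ito IKur IKr IKs IK1

typedef double (*RatesFn)(const double*, const double*, double*, double*, double*);
typedef void (*CurrentsFn)(const double*, const double*, double*);

// ---------------------------------------------------------------------------
// Courtemanche-Ramirez-Nattel 1998.  Currents in pA/pF, time ms, V mV, mM.
// States: 0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs, 10 d, 11 f,
//         12 fca, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// Params: 0 gNa, 1 gK1, 2 gto, 3 gKur_scale, 4 gKr, 5 gKs, 6 gCaL, 7 gbCa,
//         8 gbNa, 9 INaK_max, 10 INaCa_max, 11 IPMCA_max, 12 Iup_max, 13 krel
// ---------------------------------------------------------------------------
static const double CRN_R = 8.3143, CRN_T = 310.0, CRN_F = 96.4867;
static const double CRN_Cm = 100.0, CRN_Vi = 13668.0, CRN_Vup = 1109.52,
                    CRN_Vrel = 96.48;
static const double CRN_Ko = 5.4, CRN_Nao = 140.0, CRN_Cao = 1.8;
static const unsigned char CRN_GATE[21] =
  {0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0};

static void crn_cur(const double* p, const double* y, double* c) {
  const double V = y[0], m = y[1], h = y[2], j = y[3], oa = y[4], oi = y[5],
    ua = y[6], ui = y[7], xr = y[8], xs = y[9], d = y[10], f = y[11],
    fca = y[12], Nai = y[16], Ki = y[17], Cai = y[18];
  const double RTF = CRN_R * CRN_T / CRN_F;
  const double EK = RTF * log(CRN_Ko / Ki), ENa = RTF * log(CRN_Nao / Nai),
    ECa = 0.5 * RTF * log(CRN_Cao / Cai);
  const double fvrt = V / RTF;
  c[0] = p[0] * m * m * m * h * j * (V - ENa);                       // INa
  c[1] = p[8] * (V - ENa);                                          // IbNa
  c[2] = p[6] * d * f * fca * (V - 65.0);                           // ICaL
  c[3] = p[7] * (V - ECa);                                          // IbCa
  const double e1 = exp(0.35 * fvrt), e2 = exp(-0.65 * fvrt);
  c[4] = p[10] * (e1 * Nai * Nai * Nai * CRN_Cao -
                  e2 * CRN_Nao * CRN_Nao * CRN_Nao * Cai) /
    ((87.5*87.5*87.5 + CRN_Nao*CRN_Nao*CRN_Nao) * (1.38 + CRN_Cao) *
     (1.0 + 0.1 * e2));                                              // INCX
  const double sig = (exp(CRN_Nao / 67.3) - 1.0) / 7.0;
  const double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * fvrt) +
                             0.0365 * sig * exp(-fvrt));
  c[5] = p[9] * fnak / (1.0 + pow(10.0 / Nai, 1.5)) *
    (CRN_Ko / (CRN_Ko + 1.5));                                       // INKA
  c[6] = p[11] * Cai / (0.0005 + Cai);                               // IPMCA
  c[7] = p[2] * oa * oa * oa * oi * (V - EK);                        // Ito
  const double gkur = 0.005 + 0.05 / (1.0 + exp(-(V - 15.0) / 13.0));
  c[8] = p[3] * gkur * ua * ua * ua * ui * (V - EK);                 // IKur
  c[9] = p[4] * xr * (V - EK) / (1.0 + exp((V + 15.0) / 22.4));      // IKr
  c[10] = p[5] * xs * xs * (V - EK);                                 // IKs
  c[11] = p[1] * (V - EK) / (1.0 + exp(0.07 * (V + 80.0)));          // IK1
}

static double crn_rates(const double* p, const double* y, double* dy,
                        double* inf, double* tau) {
  const double V = y[0], Cai = y[18], Caup = y[19], Carel = y[20];
  double c[NCUR];
  crn_cur(p, y, c);

  // INa gates (Luo-Rudy kinetics)
  double am = (fabs(V + 47.13) < 1e-10) ? 3.2
    : 0.32 * (V + 47.13) / (1.0 - exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * exp(-V / 11.0);
  inf[1] = am / (am + bm); tau[1] = 1.0 / (am + bm);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * exp(-(V + 80.0) / 6.8);
    bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
    aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  inf[2] = ah / (ah + bh); tau[2] = 1.0 / (ah + bh);
  inf[3] = aj / (aj + bj); tau[3] = 1.0 / (aj + bj);

  // Ito gates (Q10 = 3)
  double a = 0.65 / (exp(-(V + 10.0) / 8.5) + exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + exp((V + 82.0) / 17.0));
  tau[4] = 1.0 / (3.0 * (a + b));
  inf[4] = 1.0 / (1.0 + exp(-(V + 20.47) / 17.54));
  a = 1.0 / (18.53 + exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + exp(-(V + 1.26) / 7.44));
  tau[5] = 1.0 / (3.0 * (a + b));
  inf[5] = 1.0 / (1.0 + exp((V + 43.1) / 5.3));

  // IKur gates
  a = 0.65 / (exp(-(V + 10.0) / 8.5) + exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + exp((V + 82.0) / 17.0));
  tau[6] = 1.0 / (3.0 * (a + b));
  inf[6] = 1.0 / (1.0 + exp(-(V + 30.3) / 9.6));
  a = 1.0 / (21.0 + exp(-(V - 185.0) / 28.0));
  b = exp((V - 158.0) / 16.0);
  tau[7] = 1.0 / (3.0 * (a + b));
  inf[7] = 1.0 / (1.0 + exp((V - 99.45) / 27.48));

  // IKr / IKs activation
  a = (fabs(V + 14.1) < 1e-10) ? 0.0015
    : 0.0003 * (V + 14.1) / (1.0 - exp(-(V + 14.1) / 5.0));
  b = (fabs(V - 3.3328) < 1e-10) ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1.0);
  tau[8] = 1.0 / (a + b);
  inf[8] = 1.0 / (1.0 + exp(-(V + 14.1) / 6.5));
  a = (fabs(V - 19.9) < 1e-10) ? 0.00068
    : 4e-5 * (V - 19.9) / (1.0 - exp(-(V - 19.9) / 17.0));
  b = (fabs(V - 19.9) < 1e-10) ? 0.000315
    : 3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9.0) - 1.0);
  tau[9] = 0.5 / (a + b);
  inf[9] = pow(1.0 + exp(-(V - 19.9) / 12.7), -0.5);

  // ICaL gates
  double ed = exp(-(V + 10.0) / 6.24);
  tau[10] = (fabs(V + 10.0) < 1e-10) ? 4.579 / (1.0 + ed)
    : (1.0 - ed) / (0.035 * (V + 10.0) * (1.0 + ed));
  inf[10] = 1.0 / (1.0 + exp(-(V + 10.0) / 8.0));
  inf[11] = 1.0 / (1.0 + exp((V + 28.0) / 6.9));
  tau[11] = 9.0 / (0.0197 * exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  inf[12] = 1.0 / (1.0 + Cai / 0.00035);
  tau[12] = 2.0;

  // SR release gates (driven by Fn) and w
  const double Irel = p[13] * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  const double Fn = 1e-12 * CRN_Vrel * Irel -
    5e-13 / CRN_F * (0.5 * c[2] * CRN_Cm - 0.2 * c[4] * CRN_Cm);
  inf[13] = 1.0 / (1.0 + exp(-(Fn - 3.4175e-13) / 13.67e-16));
  tau[13] = 8.0;
  inf[14] = 1.0 - 1.0 / (1.0 + exp(-(Fn - 6.835e-14) / 13.67e-16));
  tau[14] = 1.91 + 2.09 / (1.0 + exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double ew = exp(-(V - 7.9) / 5.0);
  tau[15] = (fabs(V - 7.9) < 1e-10) ? 6.0 * 0.2 / 1.3
    : 6.0 * (1.0 - ew) / ((1.0 + 0.3 * ew) * (V - 7.9));
  inf[15] = 1.0 - 1.0 / (1.0 + exp(-(V - 40.0) / 17.0));

  // Concentrations (fluxes in mM/ms; currents converted to pA via Cm)
  const double FVi = CRN_F * CRN_Vi;
  dy[16] = (-3.0 * c[5] - 3.0 * c[4] - c[1] - c[0]) * CRN_Cm / FVi;
  dy[17] = (2.0 * c[5] - c[11] - c[7] - c[8] - c[9] - c[10]) * CRN_Cm / FVi;
  const double Iup = p[12] / (1.0 + 0.00092 / Cai);
  const double Iupleak = p[12] * Caup / 15.0;
  const double Itr = (Caup - Carel) / 180.0;
  const double B1 = (2.0 * c[4] - c[6] - c[2] - c[3]) * CRN_Cm /
    (2.0 * FVi) + (CRN_Vup * (Iupleak - Iup) + Irel * CRN_Vrel) / CRN_Vi;
  const double B2 = 1.0 + 0.07 * 0.0005 / pow(Cai + 0.0005, 2) +
    0.05 * 0.00238 / pow(Cai + 0.00238, 2);
  dy[18] = B1 / B2;
  dy[19] = Iup - Iupleak - Itr * CRN_Vrel / CRN_Vup;
  dy[20] = (Itr - Irel) / (1.0 + 10.0 * 0.8 / pow(Carel + 0.8, 2));

  double isum = 0.0;
  for (int k = 0; k < NCUR; ++k) isum += c[k];
  return -isum;  // mV/ms (currents are per pF)
}

// ---------------------------------------------------------------------------
// Nygren et al. 1998 / Maleckar et al. 2009.  Native units: currents pA,
// time s, V mV, mM, Cm = 0.05 nF.  Converted to ms at the interface.
// States: 0 V, 1 m, 2 h1, 3 h2, 4 dL, 5 fL1, 6 fL2, 7 r, 8 s,
//         9 rsus|aur, 10 ssus|iur, 11 n, 12 pa, 13 Nac, 14 Kc, 15 Cac,
//         16 Nai, 17 Ki, 18 Cai, 19 Cad, 20 OC, 21 OTC, 22 OTMgC, 23 OTMgMg,
//         24 OCalse, 25 Caup, 26 Carel, 27 F1, 28 F2
// Params: 0 PNa, 1 gCaL, 2 gt, 3 gsus, 4 gKs, 5 gKr, 6 gK1, 7 gbNa, 8 gbCa,
//         9 INaK_max, 10 ICaP_max, 11 kNaCa, 12 Iup_max, 13 alpha_rel,
//         14 phi_Na_en, 15 ACh
// ---------------------------------------------------------------------------
static const double NYG_R = 8314.0, NYG_T = 306.15, NYG_F = 96487.0;
static const double NYG_Cm = 0.05;  // nF
static const double NYG_Voli = 0.005884, NYG_Vold = 0.00011768,
  NYG_Volc = 0.000800224, NYG_Volup = 0.0003969, NYG_Volrel = 0.0000441;
static const double NYG_Nab = 130.0, NYG_Kb = 5.4, NYG_Cab = 1.8;
static const double NYG_Mgi = 2.5;
static const unsigned char NYG_GATE[29] =
  {0,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0};

static void nm_cur(const double* p, const double* y, double* c, bool mal) {
  const double V = y[0], m = y[1], h1 = y[2], h2 = y[3], dL = y[4],
    fL1 = y[5], fL2 = y[6], r = y[7], s = y[8], rs = y[9], ss = y[10],
    n = y[11], pa = y[12], Nac = y[13], Kc = y[14], Cac = y[15],
    Nai = y[16], Ki = y[17], Cai = y[18], Cad = y[19];
  const double RTF = NYG_R * NYG_T / NYG_F;
  const double ENa = RTF * log(Nac / Nai), EK = RTF * log(Kc / Ki),
    ECa = 0.5 * RTF * log(Cac / Cai);
  const double x = V / RTF;
  // GHK-type INa driving term with removable singularity at V = 0
  double drive;
  if (fabs(x) < 1e-6) drive = RTF * (1.0 - x / 2.0);
  else drive = V / (exp(x) - 1.0);
  c[0] = p[0] * m * m * m * (0.9 * h1 + 0.1 * h2) * Nac * NYG_F / RTF *
    (exp((V - ENa) / RTF) - 1.0) * drive;                             // INa
  c[1] = p[7] * (V - ENa);                                            // IbNa
  const double fCa = Cad / (Cad + 0.025);
  c[2] = p[1] * dL * (fCa * fL1 + (1.0 - fCa) * fL2) * (V - 60.0);    // ICaL
  c[3] = p[8] * (V - ECa);                                            // IbCa
  c[4] = p[11] * (Nai*Nai*Nai * Cac * exp(0.45 * x) -
                  Nac*Nac*Nac * Cai * exp(-0.55 * x)) /
    (1.0 + 0.0003 * (Nac*Nac*Nac * Cai + Nai*Nai*Nai * Cac));         // INCX
  const double nai15 = pow(Nai, 1.5);
  c[5] = p[9] * Kc / (Kc + 1.0) * nai15 / (nai15 + pow(11.0, 1.5)) *
    (V + 150.0) / (V + 200.0);                                        // INKA
  c[6] = p[10] * Cai / (Cai + 0.0002);                                // IPMCA
  c[7] = p[2] * r * s * (V - EK);                                     // Ito
  c[8] = p[3] * rs * ss * (V - EK);                                   // IKur/Isus
  const double pi_kr = 1.0 / (1.0 + exp((V + 55.0) / 24.0));
  c[9] = p[5] * pa * pi_kr * (V - EK);                                // IKr
  c[10] = p[4] * n * (V - EK);                                        // IKs
  c[11] = p[6] * pow(Kc, 0.4457) * (V - EK) /
    (1.0 + exp(1.5 * (V - EK + 3.6) / RTF));                          // IK1
  (void)mal;
}

static double nm_rates_impl(const double* p, const double* y, double* dy,
                            double* inf, double* tau, bool mal) {
  const double V = y[0], Nac = y[13], Kc = y[14], Cac = y[15],
    Cai = y[18], Cad = y[19], OC = y[20], OTC = y[21], OTMgC = y[22],
    OTMgMg = y[23], OCalse = y[24], Caup = y[25], Carel = y[26],
    F1 = y[27], F2 = y[28];
  double c[NCUR];
  nm_cur(p, y, c, mal);
  const double RTF = NYG_R * NYG_T / NYG_F;

  // gate kinetics; taus in seconds here, converted below
  inf[1] = 1.0 / (1.0 + exp(-(V + 27.12) / 8.21));
  tau[1] = 4.2e-5 * exp(-pow((V + 25.57) / 28.8, 2)) + 2.4e-5;
  const double hinf = 1.0 / (1.0 + exp((V + 63.6) / 5.3));
  inf[2] = hinf; tau[2] = 0.03 / (1.0 + exp((V + 35.1) / 3.2)) + 0.0003;
  inf[3] = hinf; tau[3] = 0.12 / (1.0 + exp((V + 35.1) / 3.2)) + 0.003;
  inf[4] = 1.0 / (1.0 + exp(-(V + 9.0) / 5.8));
  tau[4] = 0.0027 * exp(-pow((V + 35.0) / 30.0, 2)) + 0.002;
  const double flinf = 1.0 / (1.0 + exp((V + 27.4) / 7.1));
  inf[5] = flinf; tau[5] = 0.161 * exp(-pow((V + 40.0) / 14.4, 2)) + 0.01;
  inf[6] = flinf; tau[6] = 1.3323 * exp(-pow((V + 40.0) / 14.2, 2)) + 0.0626;
  inf[7] = 1.0 / (1.0 + exp(-(V - 1.0) / 11.0));
  tau[7] = 0.0035 * exp(-pow(V / 30.0, 2)) + 0.0015;
  inf[8] = 1.0 / (1.0 + exp((V + 40.5) / 11.5));
  if (mal)
    tau[8] = 0.025635 * exp(-pow((V + 52.45) / 15.8827, 2)) + 0.01414;
  else
    tau[8] = 0.4812 * exp(-pow((V + 52.45) / 14.97, 2)) + 0.01414;
  if (mal) {
    inf[9] = 1.0 / (1.0 + exp(-(V + 6.0) / 8.6));
    tau[9] = 0.009 / (1.0 + exp((V + 5.0) / 12.0)) + 0.0005;
    inf[10] = 1.0 / (1.0 + exp((V + 7.5) / 10.0));
    tau[10] = 0.59 / (1.0 + exp((V + 60.0) / 10.0)) + 3.05;
  } else {
    inf[9] = 1.0 / (1.0 + exp(-(V + 4.3) / 8.0));
    tau[9] = 0.009 / (1.0 + exp((V + 5.0) / 12.0)) + 0.0005;
    inf[10] = 0.4 / (1.0 + exp((V + 20.0) / 10.0)) + 0.6;
    tau[10] = 0.047 / (1.0 + exp((V + 60.0) / 10.0)) + 0.3;
  }
  inf[11] = 1.0 / (1.0 + exp(-(V - 19.9) / 12.7));
  tau[11] = 0.7 + 0.4 * exp(-pow((V - 20.0) / 20.0, 2));
  inf[12] = 1.0 / (1.0 + exp(-(V + 15.0) / 6.0));
  tau[12] = 0.03118 + 0.21718 * exp(-pow((V + 20.1376) / 22.1996, 2));
  for (int g = 1; g <= 12; ++g) tau[g] *= 1000.0;  // s -> ms

  // optional acetylcholine-activated K+ current (Maleckar lineage)
  double ikach = 0.0;
  if (mal && p[15] > 1e-12) {
    // conductance expressed per pF; Cm = 50 pF
    ikach = 10.0 / (1.0 + 9.13652 / pow(p[15], 0.477811)) *
      (0.0517 + 0.4516 / (1.0 + exp((V + 59.53) / 17.18))) *
      (V - RTF * log(Kc / y[17])) * 50.0;
  }

  // cleft and intracellular ion balances (per second)
  const double FVc = NYG_F * NYG_Volc, FVi = NYG_F * NYG_Voli;
  const double jna = c[0] + c[1] + 3.0 * c[5] + 3.0 * c[4] + p[14];
  const double jk = c[7] + c[8] + c[11] + c[9] + c[10] + ikach - 2.0 * c[5];
  const double jca = c[2] + c[3] + c[6] - 2.0 * c[4];
  dy[13] = (NYG_Nab - Nac) / 14.3 + jna / FVc;
  dy[14] = (NYG_Kb - Kc) / 10.0 + jk / FVc;
  dy[15] = (NYG_Cab - Cac) / 24.7 + jca / (2.0 * FVc);
  dy[16] = -jna / FVi;
  dy[17] = -jk / FVi;

  // diadic space and cytosolic Ca with buffering
  const double idi = (Cad - Cai) * 2.0 * NYG_F * NYG_Vold / 0.01;
  dy[19] = -(c[2] + idi) / (2.0 * NYG_Vold * NYG_F);
  const double jOC = 200000.0 * Cai * (1.0 - OC) - 476.0 * OC;
  const double jOTC = 78400.0 * Cai * (1.0 - OTC) - 392.0 * OTC;
  const double jOTMgC = 200000.0 * Cai * (1.0 - OTMgC - OTMgMg) - 6.6 * OTMgC;
  const double jOTMgMg = 2000.0 * NYG_Mgi * (1.0 - OTMgC - OTMgMg) -
    666.0 * OTMgMg;
  dy[20] = jOC; dy[21] = jOTC; dy[22] = jOTMgC; dy[23] = jOTMgMg;
  const double dOdt = 0.08 * jOTC + 0.16 * jOTMgC + 0.045 * jOC;

  // SR uptake, transfer, release
  const double iup = p[12] * (Cai / 0.0003 - 0.16 * Caup / 0.5) /
    ((Cai + 0.0003) / 0.0003 + 0.4 * (Caup + 0.5) / 0.5);
  const double itr = (Caup - Carel) * 2.0 * NYG_F * NYG_Volrel / 0.01;
  const double relf = F2 / (F2 + 0.25);
  const double irel = p[13] * relf * relf * (Carel - Cai);
  const double acti = pow(Cai / (Cai + 0.0003), 4);
  const double actd = pow(Cad / (Cad + 0.003), 4);
  const double ract = 203.8 * (acti + actd);
  const double rinact = 33.96 + 339.6 * acti;
  dy[27] = 0.815 * (1.0 - F1 - F2) - ract * F1;
  dy[28] = ract * F1 - rinact * F2;
  const double jOCalse = 480.0 * Carel * (1.0 - OCalse) - 400.0 * OCalse;
  dy[24] = jOCalse;
  dy[18] = -(c[3] + c[6] + iup - idi - irel - 2.0 * c[4]) /
    (2.0 * NYG_Voli * NYG_F) - dOdt;
  dy[25] = (iup - itr) / (2.0 * NYG_Volup * NYG_F);
  dy[26] = (itr - irel) / (2.0 * NYG_Volrel * NYG_F) - 31.0 * jOCalse;

  for (int i = 13; i <= 28; ++i) dy[i] /= 1000.0;  // per s -> per ms

  double isum = ikach;
  for (int k = 0; k < NCUR; ++k) isum += c[k];
  return -isum / NYG_Cm / 1000.0;  // pA / nF = mV/s -> mV/ms
}

static double nyg_rates(const double* p, const double* y, double* dy,
                        double* inf, double* tau) {
  return nm_rates_impl(p, y, dy, inf, tau, false);
}
static double mal_rates(const double* p, const double* y, double* dy,
                        double* inf, double* tau) {
  return nm_rates_impl(p, y, dy, inf, tau, true);
}
static void nyg_cur(const double* p, const double* y, double* c) {
  nm_cur(p, y, c, false);
}
static void mal_cur(const double* p, const double* y, double* c) {
  nm_cur(p, y, c, true);
}

// ---------------------------------------------------------------------------
// Mock excitable cell: Mitchell-Schaeffer two-variable kinetics, with the
// activator mapped onto [rmp, rmp + amplitude] mV.  The recovery gate h is a
// Rush-Larsen-eligible gate with voltage-dependent piecewise inf/tau.
// States: 0 V (mV), 1 h.  Params: 0 rmp, 1 amplitude, 2 tau_in, 3 tau_out,
// 4 tau_open, 5 tau_close, 6 v_gate (all taus ms, v_gate on the u scale).
// ---------------------------------------------------------------------------
static const unsigned char MOCK_GATE[2] = {0, 1};

static double mock_rates(const double* p, const double* y, double* dy,
                         double* inf, double* tau) {
  const double u = (y[0] - p[0]) / p[1], h = y[1];
  if (u < p[6]) { inf[1] = 1.0; tau[1] = p[4]; }
  else          { inf[1] = 0.0; tau[1] = p[5]; }
  (void)dy;
  return p[1] * (h * u * u * (1.0 - u) / p[2] - u / p[3]);
}
static void mock_cur(const double* p, const double* y, double* c) {
  for (int k = 0; k < NCUR; ++k) c[k] = 0.0;
  (void)p; (void)y;
}

// ---------------------------------------------------------------------------
// voltage lookup tables
//
// All purely voltage-dependent quantities (gate steady states, the
// Rush-Larsen factors exp(-dt/tau(V)) for a fixed step, and the voltage
// factors of the currents) are tabulated on a 0.02 mV grid over
// [-150, 100] mV and linearly interpolated.  Interpolation error is below
// 1e-8 relative; tables are parameter-free (conductances multiply the
// interpolated factors), so control and cAF variants share them.  Tables are
// cached per (model, dt).
// ---------------------------------------------------------------------------
struct Lut {
  double v0, dv, inv_dv, dt;
  int n, ncol;
  bool ready;
  std::vector<double> d;
  Lut() : ready(false) {}
};
static Lut g_lut[3];

#define LUT_V0   (-150.0)
#define LUT_V1   (100.0)
#define LUT_DV   (0.02)

// column counts: 12 gates x (inf, rl_factor) + voltage factors
#define CRN_NCOL (24 + 6)
#define NM_NCOL  (24 + 7)

static void crn_fill_row(double V, double dt, double* r) {
  double dy[MAXSTATE], inf[MAXSTATE], tau[MAXSTATE];
  double y[21];
  // neutral state: only V matters for the tabulated entries
  y[0] = V; y[1] = y[2] = y[3] = 0.5; y[4] = y[5] = y[6] = y[7] = 0.5;
  y[8] = y[9] = y[10] = y[11] = 0.5; y[12] = 0.5; y[13] = 0.0; y[14] = 1.0;
  y[15] = 0.5; y[16] = 11.2; y[17] = 139.0; y[18] = 1e-4; y[19] = 1.0;
  y[20] = 1.0;
  static const double pneutral[14] = {7.8, 0.09, 0.1652, 1.0, 0.029411765,
    0.12941176, 0.12375, 0.001131, 0.0006744375, 0.59933874, 1600, 0.275,
    0.005, 30};
  crn_rates(pneutral, y, dy, inf, tau);
  // gates m h j oa oi ua ui xr xs d f w  (state idx 1..11, 15)
  static const int gi[12] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
  for (int q = 0; q < 12; ++q) {
    r[2 * q] = inf[gi[q]];
    r[2 * q + 1] = exp(-dt / tau[gi[q]]);
  }
  const double RTF = CRN_R * CRN_T / CRN_F;
  const double fvrt = V / RTF;
  r[24] = 0.005 + 0.05 / (1.0 + exp(-(V - 15.0) / 13.0));       // gKur(V)
  r[25] = 1.0 / (1.0 + exp((V + 15.0) / 22.4));                 // IKr factor
  r[26] = 1.0 / (1.0 + exp(0.07 * (V + 80.0)));                 // IK1 factor
  r[27] = exp(0.35 * fvrt);                                     // INCX e1
  r[28] = exp(-0.65 * fvrt);                                    // INCX e2
  const double sig = (exp(CRN_Nao / 67.3) - 1.0) / 7.0;
  r[29] = 1.0 / (1.0 + 0.1245 * exp(-0.1 * fvrt) +
                 0.0365 * sig * exp(-fvrt));                    // fNaK
}

static void nm_fill_row(double V, double dt, double* r, bool mal) {
  double dy[MAXSTATE], inf[MAXSTATE], tau[MAXSTATE];
  double y[29];
  for (int i = 0; i < 29; ++i) y[i] = 0.5;
  y[0] = V; y[13] = 130.0; y[14] = 5.4; y[15] = 1.8; y[16] = 8.5;
  y[17] = 129.4; y[18] = 6.7e-5; y[19] = 7.2e-5;
  static const double pneutral[16] = {0.0016, 6.75, 7.5, 2.75, 1.0, 0.5,
    3.0, 0.060599, 0.078681, 70.8253, 4.0, 0.0374842, 2800, 200000, 0, 0};
  nm_rates_impl(pneutral, y, dy, inf, tau, mal);
  for (int q = 1; q <= 12; ++q) {
    r[2 * (q - 1)] = inf[q];
    r[2 * (q - 1) + 1] = exp(-dt / tau[q]);
  }
  const double RTF = NYG_R * NYG_T / NYG_F;
  const double x = V / RTF;
  r[24] = exp(x);                                               // e^(VF/RT)
  r[25] = (fabs(x) < 1e-6) ? RTF * (1.0 - x / 2.0)
    : V / (exp(x) - 1.0);                                       // GHK drive
  r[26] = exp(0.45 * x);                                        // INCX
  r[27] = exp(-0.55 * x);
  r[28] = exp(1.5 * (V + 3.6) / RTF);                           // IK1
  r[29] = 1.0 / (1.0 + exp((V + 55.0) / 24.0));                 // IKr pi
  r[30] = (V + 150.0) / (V + 200.0);                            // INaK
}

static const Lut& get_lut(int model, double dt) {
  Lut& L = g_lut[model];
  if (L.ready && L.dt == dt) return L;
  L.v0 = LUT_V0; L.dv = LUT_DV; L.inv_dv = 1.0 / LUT_DV; L.dt = dt;
  L.n = (int)((LUT_V1 - LUT_V0) / LUT_DV) + 2;
  L.ncol = (model == 0) ? CRN_NCOL : NM_NCOL;
  L.d.assign((size_t)L.n * L.ncol, 0.0);
  for (int k = 0; k < L.n; ++k) {
    double V = LUT_V0 + k * LUT_DV;
    if (model == 0) crn_fill_row(V, dt, &L.d[(size_t)k * L.ncol]);
    else nm_fill_row(V, dt, &L.d[(size_t)k * L.ncol], model == 2);
  }
  L.ready = true;
  return L;
}

// interpolated row access
struct LutRow {
  const double* a;
  const double* b;
  double f;
  inline double operator()(int c) const { return a[c] + f * (b[c] - a[c]); }
};

static inline LutRow lut_row(const Lut& L, double V) {
  double u = (V - L.v0) * L.inv_dv;
  if (u < 0.0) u = 0.0;
  if (u > L.n - 2) u = L.n - 2;
  const int i0 = (int)u;
  LutRow r;
  r.a = &L.d[(size_t)i0 * L.ncol];
  r.b = r.a + L.ncol;
  r.f = u - i0;
  return r;
}

// Courtemanche step via lookup tables: returns total dV/dt used
static inline double crn_step_lut(const Lut& L, const double* p, double* y,
                                  double dt, double ext) {
  const double V = y[0], fca = y[12], u = y[13], v = y[14],
    Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];
  const LutRow r = lut_row(L, V);
  // gates advance first (Rush-Larsen at the current voltage); the ionic
  // currents then use the end-of-step gate values, which halves the
  // leading temporal error of the voltage update
  static const int gi_pre[12] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
  for (int q = 0; q < 12; ++q) {
    const double inf = r(2 * q), E = r(2 * q + 1);
    double yn = inf + (y[gi_pre[q]] - inf) * E;
    if (yn < 0.0) yn = 0.0; else if (yn > 1.0) yn = 1.0;
    y[gi_pre[q]] = yn;
  }
  const double RTF = CRN_R * CRN_T / CRN_F;
  const double EK = RTF * log(CRN_Ko / Ki), ENa = RTF * log(CRN_Nao / Nai),
    ECa = 0.5 * RTF * log(CRN_Cao / Cai);
  double c[NCUR];
  c[0] = p[0] * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
  c[1] = p[8] * (V - ENa);
  c[2] = p[6] * y[10] * y[11] * fca * (V - 65.0);
  c[3] = p[7] * (V - ECa);
  const double e1 = r(27), e2 = r(28);
  c[4] = p[10] * (e1 * Nai * Nai * Nai * CRN_Cao -
                  e2 * CRN_Nao * CRN_Nao * CRN_Nao * Cai) /
    ((87.5*87.5*87.5 + CRN_Nao*CRN_Nao*CRN_Nao) * (1.38 + CRN_Cao) *
     (1.0 + 0.1 * e2));
  c[5] = p[9] * r(29) / (1.0 + pow(10.0 / Nai, 1.5)) *
    (CRN_Ko / (CRN_Ko + 1.5));
  c[6] = p[11] * Cai / (0.0005 + Cai);
  c[7] = p[2] * y[4] * y[4] * y[4] * y[5] * (V - EK);
  c[8] = p[3] * r(24) * y[6] * y[6] * y[6] * y[7] * (V - EK);
  c[9] = p[4] * y[8] * (V - EK) * r(25);
  c[10] = p[5] * y[9] * y[9] * (V - EK);
  c[11] = p[1] * (V - EK) * r(26);

  const double Irel = p[13] * u * u * v * y[15] * (Carel - Cai);
  const double Fn = 1e-12 * CRN_Vrel * Irel -
    5e-13 / CRN_F * (0.5 * c[2] * CRN_Cm - 0.2 * c[4] * CRN_Cm);
  const double uinf = 1.0 / (1.0 + exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double vinf = 1.0 - 1.0 / (1.0 + exp(-(Fn - 6.835e-14) / 13.67e-16));
  const double tauv = 1.91 + 2.09 * uinf;

  const double FVi = CRN_F * CRN_Vi;
  const double dNai = (-3.0 * c[5] - 3.0 * c[4] - c[1] - c[0]) * CRN_Cm / FVi;
  const double dKi = (2.0 * c[5] - c[11] - c[7] - c[8] - c[9] - c[10]) *
    CRN_Cm / FVi;
  const double Iup = p[12] / (1.0 + 0.00092 / Cai);
  const double Iupleak = p[12] * Caup / 15.0;
  const double Itr = (Caup - Carel) / 180.0;
  const double B1 = (2.0 * c[4] - c[6] - c[2] - c[3]) * CRN_Cm /
    (2.0 * FVi) + (CRN_Vup * (Iupleak - Iup) + Irel * CRN_Vrel) / CRN_Vi;
  const double B2 = 1.0 + 0.07 * 0.0005 / pow(Cai + 0.0005, 2) +
    0.05 * 0.00238 / pow(Cai + 0.00238, 2);
  const double dCaup = Iup - Iupleak - Itr * CRN_Vrel / CRN_Vup;
  const double dCarel = (Itr - Irel) /
    (1.0 + 10.0 * 0.8 / pow(Carel + 0.8, 2));

  double isum = 0.0;
  for (int k = 0; k < NCUR; ++k) isum += c[k];
  const double dv = -isum + ext;

  y[0] += dt * dv;
  const double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  y[12] = fcainf + (fca - fcainf) * exp(-dt / 2.0);
  y[13] = uinf + (u - uinf) * exp(-dt / 8.0);
  y[14] = vinf + (v - vinf) * exp(-dt / tauv);
  y[16] += dt * dNai;
  y[17] += dt * dKi;
  y[18] += dt * B1 / B2;
  y[19] += dt * dCaup;
  y[20] += dt * dCarel;
  return dv;
}

// Nygren / Maleckar step via lookup tables
static inline double nm_step_lut(const Lut& L, const double* p, double* y,
                                 double dt, double ext, bool mal) {
  const double V = y[0], Nac = y[13], Kc = y[14], Cac = y[15],
    Nai = y[16], Ki = y[17], Cai = y[18], Cad = y[19], OC = y[20],
    OTC = y[21], OTMgC = y[22], OTMgMg = y[23], OCalse = y[24],
    Caup = y[25], Carel = y[26], F1 = y[27], F2 = y[28];
  const LutRow r = lut_row(L, V);
  for (int q = 1; q <= 12; ++q) {
    const double inf = r(2 * (q - 1)), E = r(2 * (q - 1) + 1);
    double yn = inf + (y[q] - inf) * E;
    if (yn < 0.0) yn = 0.0; else if (yn > 1.0) yn = 1.0;
    y[q] = yn;
  }
  const double RTF = NYG_R * NYG_T / NYG_F;
  const double EK = RTF * log(Kc / Ki), ECa = 0.5 * RTF * log(Cac / Cai);
  double c[NCUR];
  // GHK INa rewritten so E_Na never appears:
  //   Nac*(exp((V-ENa)F/RT)-1) = exp(VF/RT)*Nai - Nac
  c[0] = p[0] * y[1] * y[1] * y[1] * (0.9 * y[2] + 0.1 * y[3]) *
    NYG_F / RTF * (r(24) * Nai - Nac) * r(25);
  c[1] = p[7] * (V - RTF * log(Nac / Nai));
  const double fCa = Cad / (Cad + 0.025);
  c[2] = p[1] * y[4] * (fCa * y[5] + (1.0 - fCa) * y[6]) * (V - 60.0);
  c[3] = p[8] * (V - ECa);
  c[4] = p[11] * (Nai*Nai*Nai * Cac * r(26) - Nac*Nac*Nac * Cai * r(27)) /
    (1.0 + 0.0003 * (Nac*Nac*Nac * Cai + Nai*Nai*Nai * Cac));
  const double nai15 = Nai * sqrt(Nai);
  c[5] = p[9] * Kc / (Kc + 1.0) * nai15 / (nai15 + 36.4828726939094) *
    r(30);
  c[6] = p[10] * Cai / (Cai + 0.0002);
  c[7] = p[2] * y[7] * y[8] * (V - EK);
  c[8] = p[3] * y[9] * y[10] * (V - EK);
  c[9] = p[5] * y[12] * r(29) * (V - EK);
  c[10] = p[4] * y[11] * (V - EK);
  // IK1: 1/(1+exp(1.5(V-EK+3.6)F/RT)) = 1/(1+e_tab*(Ki/Kc)^1.5)
  const double kr = Ki / Kc;
  c[11] = p[6] * pow(Kc, 0.4457) * (V - EK) /
    (1.0 + r(28) * kr * sqrt(kr));

  double ikach = 0.0;
  if (mal && p[15] > 1e-12) {
    ikach = 10.0 / (1.0 + 9.13652 / pow(p[15], 0.477811)) *
      (0.0517 + 0.4516 / (1.0 + exp((V + 59.53) / 17.18))) * (V - EK) *
      50.0;
  }

  const double FVc = NYG_F * NYG_Volc, FVi = NYG_F * NYG_Voli;
  const double jna = c[0] + c[1] + 3.0 * c[5] + 3.0 * c[4] + p[14];
  const double jk = c[7] + c[8] + c[11] + c[9] + c[10] + ikach - 2.0 * c[5];
  const double jca = c[2] + c[3] + c[6] - 2.0 * c[4];
  const double idi = (Cad - Cai) * 2.0 * NYG_F * NYG_Vold / 0.01;
  const double jOC = 200000.0 * Cai * (1.0 - OC) - 476.0 * OC;
  const double jOTC = 78400.0 * Cai * (1.0 - OTC) - 392.0 * OTC;
  const double jOTMgC = 200000.0 * Cai * (1.0 - OTMgC - OTMgMg) -
    6.6 * OTMgC;
  const double jOTMgMg = 2000.0 * NYG_Mgi * (1.0 - OTMgC - OTMgMg) -
    666.0 * OTMgMg;
  const double dOdt = 0.08 * jOTC + 0.16 * jOTMgC + 0.045 * jOC;
  const double iup = p[12] * (Cai / 0.0003 - 0.16 * Caup / 0.5) /
    ((Cai + 0.0003) / 0.0003 + 0.4 * (Caup + 0.5) / 0.5);
  const double itr = (Caup - Carel) * 2.0 * NYG_F * NYG_Volrel / 0.01;
  const double relf = F2 / (F2 + 0.25);
  const double irel = p[13] * relf * relf * (Carel - Cai);
  const double ai = Cai / (Cai + 0.0003), ad = Cad / (Cad + 0.003);
  const double acti = ai * ai * ai * ai, actd = ad * ad * ad * ad;
  const double ract = 203.8 * (acti + actd);
  const double rinact = 33.96 + 339.6 * acti;
  const double jOCalse = 480.0 * Carel * (1.0 - OCalse) - 400.0 * OCalse;

  double isum = ikach;
  for (int k = 0; k < NCUR; ++k) isum += c[k];
  const double dv = -isum / NYG_Cm / 1000.0 + ext;

  y[0] += dt * dv;
  const double s = dt / 1000.0;  // native rates are per second
  y[13] += s * ((NYG_Nab - Nac) / 14.3 + jna / FVc);
  y[14] += s * ((NYG_Kb - Kc) / 10.0 + jk / FVc);
  y[15] += s * ((NYG_Cab - Cac) / 24.7 + jca / (2.0 * FVc));
  y[16] += s * (-jna / FVi);
  y[17] += s * (-jk / FVi);
  y[18] += s * (-(c[3] + c[6] + iup - idi - irel - 2.0 * c[4]) /
                (2.0 * NYG_Voli * NYG_F) - dOdt);
  y[19] += s * (-(c[2] + idi) / (2.0 * NYG_Vold * NYG_F));
  y[20] += s * jOC;
  y[21] += s * jOTC;
  y[22] += s * jOTMgC;
  y[23] += s * jOTMgMg;
  y[24] += s * jOCalse;
  y[25] += s * ((iup - itr) / (2.0 * NYG_Volup * NYG_F));
  y[26] += s * ((itr - irel) / (2.0 * NYG_Volrel * NYG_F) - 31.0 * jOCalse);
  y[27] += s * (0.815 * (1.0 - F1 - F2) - ract * F1);
  y[28] += s * (ract * F1 - rinact * F2);
  return dv;
}

// ---------------------------------------------------------------------------
// dispatch
// ---------------------------------------------------------------------------
struct Model {
  int id, ns;
  RatesFn rates;
  CurrentsFn cur;
  const unsigned char* gate;
};

static Model get_model(int id) {
  Model M;
  M.id = id;
  switch (id) {
  case 0: M.ns = 21; M.rates = crn_rates; M.cur = crn_cur; M.gate = CRN_GATE; break;
  case 1: M.ns = 29; M.rates = nyg_rates; M.cur = nyg_cur; M.gate = NYG_GATE; break;
  case 2: M.ns = 29; M.rates = mal_rates; M.cur = mal_cur; M.gate = NYG_GATE; break;
  case 3: M.ns = 2;  M.rates = mock_rates; M.cur = mock_cur; M.gate = MOCK_GATE; break;
  default: stop("unknown model id");
  }
  return M;
}

static inline double step_one(const Model& M, const double* p, double* y,
                              double dt, double ext,
                              const int* rk4, int nrk4);

// step dispatch: the built-in ionic models step through the lookup tables
// unless a stiff-state RK4 override is active; the mock cell (and plugins)
// use the analytic path
static inline double do_step(const Model& M, const Lut* L, const double* p,
                             double* y, double dt, double ext,
                             const int* rk4, int nrk4) {
  if (L && nrk4 == 0) {
    if (M.id == 0) return crn_step_lut(*L, p, y, dt, ext);
    return nm_step_lut(*L, p, y, dt, ext, M.id == 2);
  }
  return step_one(M, p, y, dt, ext, rk4, nrk4);
}

static inline const Lut* maybe_lut(int id, double dt) {
  if (id <= 2) return &get_lut(id, dt);
  return 0;
}

// stimulus conversion: native stimulus amplitude units -> mV/ms added to dV/dt
static double stim_factor(int id, const double* p) {
  switch (id) {
  case 0: return 1.0;            // pA/pF
  case 1: case 2: return 0.02;   // pA / (0.05 nF) = 20 mV/s = 0.02 mV/ms
  case 3: return p[1];           // activator units/ms scaled by amplitude
  }
  return 1.0;
}

// one explicit step; returns total dV/dt used (for upstroke detection)
static inline double step_one(const Model& M, const double* p, double* y,
                              double dt, double ext,
                              const int* rk4, int nrk4) {
  double dy[MAXSTATE], inf[MAXSTATE], tau[MAXSTATE];
  const double dv = M.rates(p, y, dy, inf, tau) + ext;
  if (nrk4 > 0) {
    // classical RK4 sub-integration for flagged stiff states, holding all
    // other states at their start-of-step values
    double k1[MAXSTATE], k2[MAXSTATE], k3[MAXSTATE], k4[MAXSTATE];
    double yt[MAXSTATE], d2[MAXSTATE], i2[MAXSTATE], t2[MAXSTATE];
    for (int q = 0; q < nrk4; ++q) k1[q] = dy[rk4[q]];
    for (int i = 0; i < M.ns; ++i) yt[i] = y[i];
    for (int q = 0; q < nrk4; ++q) yt[rk4[q]] = y[rk4[q]] + 0.5 * dt * k1[q];
    M.rates(p, yt, d2, i2, t2);
    for (int q = 0; q < nrk4; ++q) k2[q] = d2[rk4[q]];
    for (int q = 0; q < nrk4; ++q) yt[rk4[q]] = y[rk4[q]] + 0.5 * dt * k2[q];
    M.rates(p, yt, d2, i2, t2);
    for (int q = 0; q < nrk4; ++q) k3[q] = d2[rk4[q]];
    for (int q = 0; q < nrk4; ++q) yt[rk4[q]] = y[rk4[q]] + dt * k3[q];
    M.rates(p, yt, d2, i2, t2);
    for (int q = 0; q < nrk4; ++q) k4[q] = d2[rk4[q]];
    for (int q = 0; q < nrk4; ++q)
      dy[rk4[q]] = (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]) / 6.0;
  }
  y[0] += dt * dv;
  for (int i = 1; i < M.ns; ++i) {
    if (M.gate[i]) {
      double yi = inf[i] + (y[i] - inf[i]) * exp(-dt / tau[i]);
      if (yi < 0.0) yi = 0.0; else if (yi > 1.0) yi = 1.0;
      y[i] = yi;
    } else {
      y[i] += dt * dy[i];
    }
  }
  return dv;
}

// [[Rcpp::export]]
int model_nstate_cpp(int model) { return get_model(model).ns; }

// [[Rcpp::export]]
List rates_cpp(int model, NumericVector params, NumericVector y) {
  Model M = get_model(model);
  if ((int)y.size() != M.ns) stop("state length mismatch");
  for (int i = 0; i < M.ns; ++i)
    if (!R_finite(y[i])) stop("non-finite state '%d'", i + 1);
  double dy[MAXSTATE], inf[MAXSTATE], tau[MAXSTATE];
  for (int i = 0; i < M.ns; ++i) { dy[i] = NA_REAL; inf[i] = NA_REAL; tau[i] = NA_REAL; }
  double dv = M.rates(REAL(params), REAL(y), dy, inf, tau);
  NumericVector d(M.ns), in(M.ns), ta(M.ns);
  LogicalVector g(M.ns);
  d[0] = dv; g[0] = false; in[0] = NA_REAL; ta[0] = NA_REAL;
  for (int i = 1; i < M.ns; ++i) {
    g[i] = (bool)M.gate[i];
    if (M.gate[i]) {
      d[i] = (inf[i] - y[i]) / tau[i];
      in[i] = inf[i]; ta[i] = tau[i];
    } else {
      d[i] = dy[i]; in[i] = NA_REAL; ta[i] = NA_REAL;
    }
  }
  return List::create(_["dy"] = d, _["inf"] = in, _["tau"] = ta, _["gate"] = g);
}

// [[Rcpp::export]]
NumericVector currents_cpp(int model, NumericVector params, NumericVector y) {
  Model M = get_model(model);
  if ((int)y.size() != M.ns) stop("state length mismatch");
  double c[NCUR];
  M.cur(REAL(params), REAL(y), c);
  NumericVector out(NCUR);
  for (int k = 0; k < NCUR; ++k) out[k] = c[k];
  return out;
}

// [[Rcpp::export]]
NumericVector step_cell_cpp(int model, NumericVector params, NumericVector y,
                            double dt, int n, double istim,
                            IntegerVector rk4_idx) {
  Model M = get_model(model);
  if ((int)y.size() != M.ns) stop("state length mismatch");
  NumericVector out = clone(y);
  double* yy = REAL(out);
  const double sf = stim_factor(model, REAL(params));
  const Lut* L = maybe_lut(model, dt);
  for (int k = 0; k < n; ++k)
    do_step(M, L, REAL(params), yy, dt, istim * sf,
            rk4_idx.size() ? INTEGER(rk4_idx) : (int*)0, rk4_idx.size());
  if (!R_finite(yy[0])) stop("V_m became non-finite during stepping");
  return out;
}

// ---------------------------------------------------------------------------
// single-cell run with pacing, sampling, per-beat upstroke statistics
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_cell_cpp(int model, NumericVector params, NumericVector y0,
                  double duration, double dt, NumericVector stim_times,
                  double stim_dur, double stim_amp, double sample_dt,
                  int cai_index, bool record_currents,
                  IntegerVector rk4_idx) {
  Model M = get_model(model);
  if ((int)y0.size() != M.ns) stop("state length mismatch");
  const double* p = REAL(params);
  const double sf = stim_factor(model, p);
  double y[MAXSTATE];
  for (int i = 0; i < M.ns; ++i) y[i] = y0[i];

  const long nsteps = (long)llround(duration / dt);
  const int sps = (int)llround(sample_dt / dt);
  if (sps < 1) stop("sample_dt must be >= dt");
  const long nsamp = nsteps / sps + 1;
  NumericVector tout(nsamp), vout(nsamp), caout(cai_index >= 0 ? nsamp : 0);
  NumericMatrix curout(record_currents ? nsamp : 0, record_currents ? NCUR : 0);

  const int nstim = stim_times.size();
  const int nwin = nstim;
  NumericMatrix wstat(nwin, 6); // t_dvdtmax, dvdtmax, dm1, dp1, vpeak, v_pre
  std::fill(wstat.begin(), wstat.end(), NA_REAL);
  for (int w = 0; w < nwin; ++w) { wstat(w, 1) = -1e300; wstat(w, 4) = -1e300; }

  const Lut* L = maybe_lut(model, dt);
  int si = 0;           // next stimulus to switch on
  int win = -1;         // current window
  double prev_dvdt = 0.0;
  long need_next = -1;  // step index whose dvdt becomes dp1 of current max
  long samp = 0;
  double c[NCUR];

  for (long k = 0; k <= nsteps; ++k) {
    const double t = k * dt;
    if (k % sps == 0 && samp < nsamp) {
      tout[samp] = t; vout[samp] = y[0];
      if (cai_index >= 0) caout[samp] = y[cai_index];
      if (record_currents) {
        M.cur(p, y, c);
        for (int q = 0; q < NCUR; ++q) curout(samp, q) = c[q];
      }
      if (!R_finite(y[0]))
        stop("V_m became non-finite at t = %f ms", t);
      ++samp;
    }
    if (k == nsteps) break;
    // stimulus bookkeeping (windows open at each stimulus onset)
    while (si < nstim && t >= stim_times[si] - 0.5 * dt) {
      win = si;
      wstat(win, 5) = y[0];  // pre-stimulus V_m
      ++si;
    }
    double istim = 0.0;
    if (win >= 0 && t < stim_times[win] + stim_dur) istim = stim_amp;
    const double dv = do_step(M, L, p, y, dt, istim * sf,
                              rk4_idx.size() ? INTEGER(rk4_idx) : (int*)0,
                              rk4_idx.size());
    // upstroke statistics use the ionic dV/dt (stimulus removed) so that
    // dV/dt_max is not inflated by the pulse amplitude
    const double dvi = dv - istim * sf;
    if (win >= 0) {
      if (k == need_next) wstat(win, 3) = dvi;
      if (dvi > wstat(win, 1)) {
        wstat(win, 1) = dvi; wstat(win, 0) = t;
        wstat(win, 2) = prev_dvdt; need_next = k + 1;
      }
      if (y[0] > wstat(win, 4)) wstat(win, 4) = y[0];
    }
    prev_dvdt = dvi;
  }

  NumericVector yfin(M.ns);
  for (int i = 0; i < M.ns; ++i) yfin[i] = y[i];
  List out = List::create(_["time"] = tout, _["vm"] = vout,
                          _["cai"] = caout, _["beats"] = wstat,
                          _["state"] = yfin);
  if (record_currents) out["currents"] = curout;
  return out;
}

// [[Rcpp::export]]
List clamp_cell_cpp(int model, NumericVector params, NumericVector y0,
                    double vhold, double duration, double dt,
                    IntegerVector rk4_idx) {
  Model M = get_model(model);
  if ((int)y0.size() != M.ns) stop("state length mismatch");
  const double* p = REAL(params);
  double y[MAXSTATE];
  for (int i = 0; i < M.ns; ++i) y[i] = y0[i];
  y[0] = vhold;
  const long nsteps = (long)llround(duration / dt);
  const Lut* L = maybe_lut(model, dt);
  for (long k = 0; k < nsteps; ++k) {
    do_step(M, L, p, y, dt, 0.0,
            rk4_idx.size() ? INTEGER(rk4_idx) : (int*)0, rk4_idx.size());
    y[0] = vhold;  // voltage clamp
  }
  double c[NCUR];
  M.cur(p, y, c);
  // residual drift diagnostic: concentration derivatives at end of clamp
  double dy[MAXSTATE], inf[MAXSTATE], tau[MAXSTATE];
  M.rates(p, y, dy, inf, tau);
  double maxd = 0.0;
  for (int i = 1; i < M.ns; ++i)
    if (!M.gate[i] && fabs(dy[i]) > maxd) maxd = fabs(dy[i]);
  NumericVector cc(NCUR), yfin(M.ns);
  for (int k = 0; k < NCUR; ++k) cc[k] = c[k];
  for (int i = 0; i < M.ns; ++i) yfin[i] = y[i];
  return List::create(_["currents"] = cc, _["state"] = yfin,
                      _["max_drift"] = maxd);
}

// ---------------------------------------------------------------------------
// 1D strand monodomain integrator (3-point Laplacian, no-flux boundaries)
// ---------------------------------------------------------------------------
// stims: matrix with columns (t0, dur, amp, from, to)  [voxel range, 0-based,
// half-open).  Site traces are sampled every sample_dt at record_sites.
// Per stimulus window w and voxel v the integrator tracks the time and value
// of the maximum total dV/dt (with its neighbours for parabolic refinement)
// and the peak V_m.
// [[Rcpp::export]]
List run_strand_cpp(int model, NumericVector params, NumericMatrix y0,
                    double dx, double D, double dt, double duration,
                    NumericMatrix stims, IntegerVector record_sites,
                    double sample_dt, double movie_dt,
                    IntegerVector rk4_idx) {
  Model M = get_model(model);
  const int nv = y0.ncol();
  if (y0.nrow() != M.ns) stop("state matrix must be n_state x n_voxels");
  const double* p = REAL(params);
  const double sf = stim_factor(model, p);
  std::vector<double> Y(y0.begin(), y0.end());  // ns x nv, column-major
  const double rdx2 = D / (dx * dx);

  const long nsteps = (long)llround(duration / dt);
  const int sps = std::max(1, (int)llround(sample_dt / dt));
  const long nsamp = nsteps / sps + 1;
  const int nsites = record_sites.size();
  NumericMatrix site_vm(nsamp, nsites);
  NumericVector site_t(nsamp);

  const int mps = movie_dt > 0 ? (int)llround(movie_dt / dt) : 0;
  const long nframes = mps > 0 ? nsteps / mps + 1 : 0;
  NumericMatrix movie(mps > 0 ? nv : 0, mps > 0 ? nframes : 0);
  NumericVector movie_t(nframes);

  const int nstim = stims.nrow();
  const int nwin = nstim;
  // per window: t_dvdtmax, dvdtmax, dm1, dp1, vpeak  (nv x 5 each)
  std::vector<NumericMatrix> wt;
  for (int w = 0; w < nwin; ++w) {
    NumericMatrix m(nv, 5);
    std::fill(m.begin(), m.end(), NA_REAL);
    for (int v = 0; v < nv; ++v) { m(v, 1) = -1e300; m(v, 4) = -1e300; }
    wt.push_back(m);
  }
  std::vector<double> lap(nv), prevd(nv, 0.0);
  std::vector<long> neednext(nv, -1);
  const Lut* L = maybe_lut(model, dt);
  int win = -1;
  long samp = 0, frame = 0;
  const int* rk4 = rk4_idx.size() ? INTEGER(rk4_idx) : (int*)0;
  const int nrk4 = rk4_idx.size();

  for (long k = 0; k <= nsteps; ++k) {
    const double t = k * dt;
    if (k % sps == 0 && samp < nsamp) {
      site_t[samp] = t;
      for (int s = 0; s < nsites; ++s)
        site_vm(samp, s) = Y[record_sites[s] * M.ns];
      if (!R_finite(Y[0]) || !R_finite(Y[(nv - 1) * M.ns]))
        stop("V_m became non-finite at t = %f ms", t);
      ++samp;
    }
    if (mps > 0 && k % mps == 0 && frame < nframes) {
      for (int v = 0; v < nv; ++v) movie(v, frame) = Y[v * M.ns];
      movie_t[frame] = t;
      ++frame;
    }
    if (k == nsteps) break;
    while (win + 1 < nstim && t >= stims(win + 1, 0) - 0.5 * dt) ++win;
    // Laplacian with no-flux (mirrored) boundaries
    for (int v = 0; v < nv; ++v) {
      const double vm = Y[v * M.ns];
      // no-flux: zero-gradient ghost (conserves the spatial mean exactly)
      const double vl = (v > 0) ? Y[(v - 1) * M.ns] : vm;
      const double vr = (v < nv - 1) ? Y[(v + 1) * M.ns] : vm;
      lap[v] = vl - 2.0 * vm + vr;
    }
    for (int v = 0; v < nv; ++v) {
      double ext = rdx2 * lap[v];
      for (int sI = 0; sI <= win && sI < nstim; ++sI) {
        if (t >= stims(sI, 0) - 0.5 * dt && t < stims(sI, 0) + stims(sI, 1) &&
            v >= (int)stims(sI, 3) && v < (int)stims(sI, 4))
          ext += stims(sI, 2) * sf;
      }
      const double dv = do_step(M, L, p, &Y[v * M.ns], dt, ext, rk4, nrk4);
      // upstroke statistics use the ionic dV/dt: on coarse grids the
      // discrete diffusion term is lumpy near the front and would jitter
      // the activation-time estimate (the stimulus term is excluded for
      // the same reason as in single cells)
      const double dvi = dv - ext;
      if (win >= 0) {
        NumericMatrix& m = wt[win];
        if (k == neednext[v]) m(v, 3) = dvi;
        if (dvi > m(v, 1)) {
          m(v, 1) = dvi; m(v, 0) = t; m(v, 2) = prevd[v];
          neednext[v] = k + 1;
        }
        const double vm = Y[v * M.ns];
        if (vm > m(v, 4)) m(v, 4) = vm;
      }
      prevd[v] = dvi;
    }
  }

  NumericMatrix yfin(M.ns, nv);
  std::copy(Y.begin(), Y.end(), yfin.begin());
  List wl(nwin);
  for (int w = 0; w < nwin; ++w) wl[w] = wt[w];
  List out = List::create(_["site_t"] = site_t, _["site_vm"] = site_vm,
                          _["windows"] = wl, _["state"] = yfin);
  if (mps > 0) { out["movie"] = movie; out["movie_t"] = movie_t; }
  return out;
}

// ---------------------------------------------------------------------------
// 2D patch monodomain integrator (5-point Laplacian, no-flux boundaries)
// ---------------------------------------------------------------------------
// stims: matrix with columns (t0, dur, amp, x0, x1, yy0, yy1) rectangle in
// voxel indices, half-open.  Movie frames record V_m of the whole grid.
// [[Rcpp::export]]
List run_patch_cpp(int model, NumericVector params, NumericMatrix y0,
                   int nx, int ny, double dx, double D, double dt,
                   double duration, NumericMatrix stims, double movie_dt,
                   bool return_state, IntegerVector rk4_idx) {
  Model M = get_model(model);
  if (y0.nrow() != M.ns) stop("state matrix must have n_state rows");
  const double* p = REAL(params);
  const double sf = stim_factor(model, p);
  const int nv = nx * ny;
  std::vector<double> Y((size_t)M.ns * nv);
  if (y0.ncol() == nv) {
    std::copy(y0.begin(), y0.end(), Y.begin());
  } else if (y0.ncol() == 1) {
    for (int v = 0; v < nv; ++v)
      for (int i = 0; i < M.ns; ++i) Y[(size_t)v * M.ns + i] = y0(i, 0);
  } else stop("state matrix must have 1 or nx*ny columns");
  const double rdx2 = D / (dx * dx);

  const long nsteps = (long)llround(duration / dt);
  const int mps = (int)llround(movie_dt / dt);
  if (mps < 1) stop("movie_dt must be >= dt");
  const long nframes = nsteps / mps + 1;
  NumericMatrix movie(nv, nframes);
  NumericVector movie_t(nframes);

  std::vector<double> lap(nv);
  const Lut* L = maybe_lut(model, dt);
  const int nstim = stims.nrow();
  long frame = 0;
  const int* rk4 = rk4_idx.size() ? INTEGER(rk4_idx) : (int*)0;
  const int nrk4 = rk4_idx.size();

  for (long k = 0; k <= nsteps; ++k) {
    const double t = k * dt;
    if (k % mps == 0 && frame < nframes) {
      for (int v = 0; v < nv; ++v) movie(v, frame) = Y[(size_t)v * M.ns];
      movie_t[frame] = t;
      if (!R_finite(Y[0])) stop("V_m became non-finite at t = %f ms", t);
      ++frame;
    }
    if (k == nsteps) break;
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int v = iy * nx + ix;
        const double vm = Y[(size_t)v * M.ns];
        const double vl = (ix > 0) ? Y[(size_t)(v - 1) * M.ns] : vm;
        const double vr = (ix < nx - 1) ? Y[(size_t)(v + 1) * M.ns] : vm;
        const double vd = (iy > 0) ? Y[(size_t)(v - nx) * M.ns] : vm;
        const double vu = (iy < ny - 1) ? Y[(size_t)(v + nx) * M.ns] : vm;
        lap[v] = vl + vr + vd + vu - 4.0 * vm;
      }
    }
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int v = iy * nx + ix;
        double ext = rdx2 * lap[v];
        for (int sI = 0; sI < nstim; ++sI) {
          if (t >= stims(sI, 0) - 0.5 * dt && t < stims(sI, 0) + stims(sI, 1) &&
              ix >= (int)stims(sI, 3) && ix < (int)stims(sI, 4) &&
              iy >= (int)stims(sI, 5) && iy < (int)stims(sI, 6))
            ext += stims(sI, 2) * sf;
        }
        do_step(M, L, p, &Y[(size_t)v * M.ns], dt, ext, rk4, nrk4);
      }
    }
  }
  List out = List::create(_["movie"] = movie, _["movie_t"] = movie_t,
                          _["nx"] = nx, _["ny"] = ny);
  if (return_state) {
    NumericMatrix yfin(M.ns, nv);
    std::copy(Y.begin(), Y.end(), yfin.begin());
    out["state"] = yfin;
  }
  return out;
}
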